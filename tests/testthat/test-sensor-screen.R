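test_that("window enumeration matches the closed form and respects bounds", {
  cfg <- screen_config()
  w <- enumerate_windows(random_rna(40), cfg)
  expect_identical(nrow(w), 27L)                     # 10 + 9 + 8
  expect_identical(nrow(enumerate_windows(random_rna(31), cfg)), 1L)
  expect_error(enumerate_windows(random_rna(30), cfg), "shorter")
  # property: count equals the closed form across random lengths
  set.seed(3)
  for (L in sample(31:120, 8)) {
    win <- enumerate_windows(random_rna(L), cfg)
    expect_identical(nrow(win),
                     sum(pmax(L - cfg$window_lengths + 1L, 0L)))
  }
  # ordering is (start, length) lexicographic
  expect_true(!is.unsorted(w$start))
  expect_identical(w$length[w$start == 1], c(31L, 32L, 33L))
})

test_that("window coordinates index the trigger exactly", {
  trig <- rna_seq(random_rna(70), id = "t")
  win <- enumerate_windows(trig, screen_config())
  for (i in sample(nrow(win), 10)) {
    expect_identical(win$window_seq[i],
                     substr(as.character(trig), win$start[i],
                            win$start[i] + win$length[i] - 1L))
  }
})

test_that("evaluation computes GC, sensor motifs and fold score as specified", {
  cfg <- screen_config()
  # the window implied by the published sensor evaluates clean
  trig <- rna_seq(published_window, id = "t")
  ev <- evaluate_windows(enumerate_windows(trig, cfg), cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$sensor_seq, published_sensor)
  expect_equal(ev$gc, 17 / 31)
  expect_identical(ev$motif_hits, "")
  expect_true(is.na(ev$offtarget_hits))
  # all-AU window fails on MMMM; poly-G window fails on GGGG
  au <- data.frame(source_id = "x", start = 1L, length = 31L,
                   window_seq = strrep("AU", 16) |> substr(1, 31))
  expect_match(evaluate_windows(au, cfg)$motif_hits, "MMMM")
  gg <- data.frame(source_id = "x", start = 1L, length = 31L,
                   window_seq = paste0(strrep("C", 27), "GGGG"))
  expect_match(evaluate_windows(gg, cfg)$motif_hits, "GGGG")
})

test_that("k-mer index equals a naive substring scan and honors exclusions", {
  set.seed(21)
  sensor <- published_sensor
  bg <- synth_background(6, lengths = 120, protected = sensor, k = 15, seed = 5)
  # clean background: zero hits both ways
  idx <- build_kmer_index(bg, k = 15)
  expect_identical(as.integer(count_offtarget_hits(sensor, idx)), 0L)
  expect_identical(naive_offtarget(sensor, bg, 15), 0L)
  # implant a sensor 15-mer into one decoy: both methods see it
  bg2 <- synth_background(6, lengths = 120, protected = sensor, k = 15, seed = 5,
                          implant = list(record = 3, pos = 40,
                                         seq = substr(sensor, 4, 18)))
  idx2 <- build_kmer_index(bg2, k = 15)
  expect_identical(as.integer(count_offtarget_hits(sensor, idx2)), 1L)
  expect_identical(naive_offtarget(sensor, bg2, 15), 1L)
  per <- attr(count_offtarget_hits(sensor, idx2), "per_record")
  expect_identical(per$id, "decoy_3")
  # the intended target (which carries the window, i.e. the sensor's
  # reverse complement) is found by the strand-agnostic lookup and must be
  # removed by id exclusion
  tgt <- rna_seq(published_window, id = "target")
  idx3 <- build_kmer_index(c(bg, list(target = tgt)), k = 15)
  expect_identical(as.integer(count_offtarget_hits(sensor, idx3)), 1L)
  expect_identical(as.integer(count_offtarget_hits(sensor, idx3,
                                                   exclude_ids = "target")), 0L)
  # oracle equivalence on random backgrounds sharing k-mers by chance (small k)
  for (rep in 1:5) {
    bgr <- lapply(1:4, function(i) rna_seq(random_rna(60), id = paste0("r", i)))
    names(bgr) <- paste0("r", 1:4)
    idxr <- build_kmer_index(bgr, k = 8)
    s <- random_rna(31)
    expect_identical(as.integer(count_offtarget_hits(s, idxr)),
                     naive_offtarget(s, bgr, 8))
  }
})

test_that("index construction skips short records with a warning and rejects empties", {
  bg <- list(a = rna_seq(random_rna(20), id = "a"),
             b = rna_seq(random_rna(10), id = "b"))
  expect_warning(idx <- build_kmer_index(bg, k = 15), "skipped")
  expect_identical(idx$record_ids, "a")
  expect_identical(length(idx$map), 6L)   # L - k + 1 distinct positions
  expect_error(build_kmer_index(list(), k = 15), "empty")
  expect_error(count_offtarget_hits("ACGUACGUACGU", idx), "shorter than k")
})

test_that("sensor of the published window is shorter-than-k safe and trigger matches count as hits", {
  # two identical records: every k-mer maps to both ids
  r <- rna_seq(random_rna(40), id = "x")
  r2 <- rna_seq(as.character(r), id = "y")
  idx <- build_kmer_index(list(x = r, y = r2), k = 15)
  expect_true(all(vapply(idx$map, function(df) setequal(df$id, c("x", "y")), logical(1))))
})

test_that("ranking is the documented deterministic total order with hard filters", {
  cfg <- screen_config()
  base <- data.frame(source_id = "t", start = c(1L, 5L, 9L, 13L),
                     length = 31L,
                     window_seq = "x", sensor_seq = "x",
                     gc = c(0.48, 0.52, 0.50, 0.50),
                     motif_hits = "", fold_score = c(3L, 3L, 4L, 2L),
                     fold_ok = TRUE, offtarget_hits = NA_integer_)
  r <- rank_candidates(base, cfg)
  # |gc-0.5| first: the two gc=0.50 rows lead, fold 2 before fold 4;
  # then the 0.48/0.52 tie broken by fold, then start
  expect_identical(r$start, c(13L, 9L, 1L, 5L))
  expect_identical(r$rank, 1:4)
  # hard filters: motif hit, GC out of bounds, off-target hits when screened
  flt <- base
  flt$motif_hits[1] <- "GGGG@2"
  flt$gc[2] <- 0.60
  flt$offtarget_hits[3] <- 1L
  r2 <- rank_candidates(flt, cfg)
  expect_identical(r2$start, 13L)
  # empty survivor set is legal
  none <- flt[1, , drop = FALSE]
  expect_identical(nrow(rank_candidates(none, cfg)), 0L)
})

test_that("tightening GC bounds is monotone: survivors only shrink", {
  trig <- synth_transcript(150, seed = 17)
  cfg_loose <- screen_config(gc_lo = 0.40, gc_hi = 0.60)
  ev <- evaluate_windows(enumerate_windows(trig, cfg_loose), cfg_loose)
  prev_keys <- NULL
  for (width in c(0.10, 0.06, 0.03, 0.01)) {
    cfg <- screen_config(gc_lo = 0.5 - width, gc_hi = 0.5 + width)
    surv <- rank_candidates(ev, cfg)
    keys <- paste(surv$start, surv$length)
    if (!is.null(prev_keys)) expect_true(all(keys %in% prev_keys))
    prev_keys <- keys
  }
})

test_that("screen config validates its invariants", {
  expect_error(screen_config(gc_lo = 0.6, gc_hi = 0.5), "lo < hi")
  expect_error(screen_config(k = 4), "k must be >= 8")
  expect_error(screen_config(window_lengths = 10:12, k = 15), ">= off-target k")
})
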