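test_that("the published triad reconstructs bit-exactly from its parts", {
  sensor <- build_sensor(published_window)
  expect_identical(as.character(sensor$seq), published_sensor)
  expect_identical(sensor$toehold, "GCGACCAA")
  expect_identical(sensor$toehold_range, c(24L, 31L))

  guide <- build_guide(published_sirna, extension = published_ext)
  expect_identical(as.character(guide$seq), published_guide)
  expect_identical(guide$overhang, "UU")

  core <- build_core(sensor, guide)
  expect_identical(as.character(core$seq), published_core)
  expect_identical(core$split, c(11L, 12L))
  expect_identical(core$segments$overhang5, c(1L, 11L))
  expect_identical(core$segments$central, c(12L, 34L))
  expect_identical(core$segments$overhang3, c(35L, 46L))
})

test_that("sensor construction enforces the toehold requirement", {
  expect_error(build_sensor(random_rna(23)), "toehold")
  s33 <- build_sensor(random_rna(33))
  expect_identical(nchar(s33$toehold), 10L)
  s24 <- build_sensor(random_rna(24))
  expect_identical(nchar(s24$toehold), 1L)
})

test_that("guide construction handles extensions, overhangs and the GC-rich rule", {
  # 23-nt pairing-only input: unchanged plus UU
  g23 <- paste0(strrep("GC", 10), "AGC")
  g <- build_guide(g23)
  expect_identical(as.character(g$seq), paste0(g23, "UU"))
  expect_identical(g$extension, "")
  # over-long paired portion is rejected
  expect_error(build_guide(paste0(random_rna(24), "GG")), "pairing region")
  # wrong extension length rejected
  expect_error(build_guide(published_sirna, extension = "CG"), "length 4")
  # AU-rich extension rejected under the >= 3-of-4 G/C rule
  expect_error(build_guide(published_sirna, extension = "AAAA"), "GC-rich")
  # the published CGAG extension (3 of 4 G/C) passes
  expect_silent(build_guide(published_sirna, extension = "CGAG"))
  # auto-extension is all G/C, correct length, and deterministic
  a1 <- build_guide(published_sirna)
  a2 <- build_guide(published_sirna)
  expect_identical(a1$extension, a2$extension)
  expect_identical(nchar(a1$extension), 4L)
  expect_true(grepl("^[GC]+$", a1$extension))
})

test_that("generalized core split follows floor/ceiling of the pairing region", {
  w <- random_rna(31)
  sensor22 <- build_sensor(w, pair_len = 22L)
  guide <- build_guide(random_rna(23), includes_overhang = FALSE)
  core <- build_core(sensor22, guide)
  expect_identical(core$split, c(11L, 11L))
  expect_identical(nchar(as.character(core$seq)), 11L + 23L + 11L)
})

test_that("assembly verifies the three duplexes and reports mismatch positions", {
  cons <- build_published_construct()
  expect_identical(unname(cons$stats$duplex_lengths), c(11L, 23L, 12L))
  expect_identical(cons$stats$toehold, "GCGACCAA")
  expect_identical(cons$stats$guide_overhang, "UU")
  expect_identical(cons$stats$sensor_paired_bases, 23L)
  # pairing map disjointness: no position claimed twice on any strand
  for (strand in c("core", "sensor", "guide")) {
    claimed <- integer(0)
    for (r in seq_len(nrow(cons$pairing))) {
      d <- cons$pairing[r, ]
      if (d$a == strand) claimed <- c(claimed, d$a_start:d$a_end)
      if (d$b == strand) claimed <- c(claimed, d$b_start:d$b_end)
    }
    expect_identical(anyDuplicated(claimed), 0L)
  }
  # one mutated sensor base is caught with its position
  mut <- published_sensor
  substr(mut, 5, 5) <- "G"   # position 5 pairs core position 7
  expect_error(assemble_construct(published_guide, mut, published_core),
               "position 7.*sensor position 5|sensor position 5")
  # strands in swapped roles cannot pair
  expect_error(assemble_construct(published_sensor, published_guide, published_core),
               "mismatch")
})

test_that("any valid window/guide pair assembles with zero mismatches", {
  set.seed(41)
  for (i in 1:15) {
    w <- random_rna(sample(31:33, 1))
    sg <- random_rna(sample(19:23, 1))
    sensor <- build_sensor(w)
    guide <- build_guide(sg, includes_overhang = FALSE)
    core <- build_core(sensor, guide)
    cons <- assemble_construct(guide, sensor, core)
    p <- 23L
    expect_identical(unname(cons$stats$duplex_lengths), c(11L, 23L, 12L))
    expect_identical(nchar(as.character(core$seq)), p %/% 2L + 23L + (p - p %/% 2L))
    expect_identical(cons$stats$toehold_length, nchar(w) - p)
    rep <- verify_assembly(cons)
    expect_true(rep$pass)
  }
})

test_that("verification reports geometry, energies and advisory warnings", {
  cons <- build_published_construct()
  rep <- verify_assembly(cons)
  expect_true(rep$pass)
  expect_identical(rep$duplexes$length, c(11L, 23L, 12L))
  expect_true(all(rep$duplexes$dG37 < 0))
  expect_identical(rep$unpaired$sensor_toehold, c(24L, 31L))
  expect_identical(rep$nick_after_core_pos, 34L)
  expect_length(rep$warnings, 0L)
  # a construct from a 33-nt window passes with a 10-nt toehold
  s33 <- build_sensor(random_rna(33))
  g33 <- build_guide(random_rna(21), includes_overhang = FALSE)
  c33 <- assemble_construct(g33, s33, build_core(s33, g33))
  rep33 <- verify_assembly(c33)
  expect_true(rep33$pass)
  expect_identical(c33$stats$toehold_length, 10L)
  # non-UU overhang is a warning, not a failure
  gAA <- build_guide(random_rna(21), includes_overhang = FALSE, overhang = "AG")
  sensor <- build_sensor(random_rna(31))
  consAA <- assemble_construct(gAA, sensor, build_core(sensor, gAA))
  repAA <- verify_assembly(consAA)
  expect_true(repAA$pass)
  expect_match(repAA$warnings, "overhang")
})
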