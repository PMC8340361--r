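test_that("ligand codes split into mono- and poly-phosphorylated classes", {
  expect_equal(pip_class(c("3", "4", "5")), rep("mono", 3))
  expect_equal(pip_class(c("34", "35", "45", "345")), rep("poly", 4))
  expect_error(pip_class("6"), "unknown ligand code")
})

test_that("LSI reproduces the published worked examples", {
  expect_equal(compute_lsi("34")$lsi, 10L)                      # single ligand
  hs1bp3 <- compute_lsi(c("3", "34", "35", "45", "345"))
  expect_equal(hs1bp3$lsi, 5L)
  expect_equal(hs1bp3$assigned_class, "poly")
  expect_equal(hs1bp3$n1, 3L)
  expect_equal(hs1bp3$n2, 1L)
  snx11 <- compute_lsi(c("3", "4", "5", "34", "35", "45", "345"))
  expect_equal(snx11$lsi, 1L)                                   # binds all 7
  snx20 <- compute_lsi(c("3", "5", "35", "45"))                 # 2-2 tie
  expect_equal(snx20$lsi, 5L)
  expect_equal(snx20$assigned_class, "tie")
  expect_equal(compute_lsi(character(0))$lsi, 0L)               # non-binder
  expect_error(compute_lsi(NA_character_), "undetermined")
  expect_error(compute_lsi(c("3", "3")), "duplicated")
})

test_that("LSI agrees with the brute-force oracle on all 2^7 ligand subsets", {
  subsets <- all_pip_subsets()
  expect_length(subsets, 128)
  for (s in subsets) {
    res <- compute_lsi(s)
    expect_equal(res$lsi, lsi_oracle(s))
    expect_true(res$lsi == 0 || (res$lsi >= 1 && res$lsi <= 10))
    if (length(s) > 0) {
      expect_equal(res$n1 + res$n2 + 1L, length(s))
      expect_equal(res$lsi, 10L - res$n1 - 2L * res$n2)
    }
  }
})

test_that("tie subsets give the same LSI under either class choice", {
  mono <- c("3", "4", "5")
  for (s in all_pip_subsets()) {
    m <- sum(s %in% mono); p <- length(s) - m
    if (length(s) > 0 && m == p) {
      as_mono <- 10L - (m - 1L) - 2L * p
      as_poly <- 10L - (p - 1L) - 2L * m
      expect_equal(as_mono, as_poly)
      expect_equal(compute_lsi(s)$lsi, as_mono)
    }
  }
})

test_that("adding a ligand never increases the LSI of a binder", {
  # LSI 0 is the non-binder sentinel, not the low end of the selectivity
  # scale, so monotonicity applies to nonempty ligand sets only
  codes <- c("3", "4", "5", "34", "35", "45", "345")
  for (s in all_pip_subsets()) {
    if (length(s) %in% c(0, 7)) next
    base <- compute_lsi(s)$lsi
    for (extra in setdiff(codes, s)) {
      expect_lte(compute_lsi(c(s, extra))$lsi, base)
    }
  }
})

test_that("selectivity classes bin the LSI range as published", {
  expect_equal(as.character(selectivity_class(c(10, 9, 8, 7, 5, 4, 1, 0))),
               c("absolute", "high", "high", "medium", "medium",
                 "low", "low", "none"))
  expect_error(selectivity_class(11), "0..10")
  expect_error(selectivity_class(-1), "0..10")
})

test_that("evidence weights follow the 1 / 2-4 / 5+ study bins", {
  expect_equal(stop_weight(c(1, 2, 3, 4, 5, 12)), c(1L, 2L, 2L, 2L, 3L, 3L))
  expect_error(stop_weight(0), "positive")
  # nondecreasing in study count
  w <- stop_weight(1:20)
  expect_true(all(diff(w) >= 0))
})

test_that("stop scores sum evidence weights over in-site modifications only", {
  seqx <- strrep("K", 20)
  w <- toy_windows()  # sites cover 3-6, 9-11, 14-17
  expect_equal(compute_stop_score(make_ptms()[0, ], seqx, w, "met")$total, 0L)
  # one in-site methylation (weight 1) plus one outside acetylation
  ptms <- make_ptms(residue_number = c(4L, 7L),
                    ptm_type = c("methylation", "acetylation"))
  expect_equal(compute_stop_score(ptms, seqx, w, "met")$total, 1L)
  # study counts 1, 3, 7 inside sites weigh 1 + 2 + 3 = 6
  ptms3 <- make_ptms(residue_number = c(4L, 9L, 15L), study_count = c(1L, 3L, 7L))
  sc <- compute_stop_score(ptms3, seqx, w, "met")
  expect_equal(sc$total, 6L)
  expect_equal(sort(sc$contributions$weight), c(1L, 2L, 3L))
  expect_setequal(sc$contributions$site, c("site1", "site2", "site3"))
  # adding another in-site modification never decreases the score
  more <- dplyr::bind_rows(ptms3, make_ptms(residue_number = 16L,
                                            ptm_type = "glycation"))
  expect_gte(compute_stop_score(more, seqx, w, "met")$total, sc$total)
})

test_that("met and pip modes select the matching chemistry", {
  seqx <- paste(rep(c("K", "S"), 10), collapse = "")
  w <- toy_windows()
  ptms <- dplyr::bind_rows(
    make_ptms(residue_number = 5L),                                  # K, met
    make_ptms(residue_letter = "S", residue_number = 4L,
              ptm_type = "phosphorylation"),                         # S, pip
    make_ptms(residue_letter = "S", residue_number = 10L,
              ptm_type = "phosphorylation")                          # in site2
  )
  expect_equal(compute_stop_score(ptms, seqx, w, "met")$total, 1L)
  expect_equal(compute_stop_score(ptms, seqx, w, "pip")$total, 2L)
  # species filter restricts which records count
  expect_equal(compute_stop_score(ptms, seqx, w, "met",
                                  species = "M. musculus")$total, 0L)
  # per-species records pool within species, not across
  cross <- make_ptms(species = c("H. sapiens", "M. musculus"),
                     residue_number = 5L, study_count = 1L)
  expect_equal(compute_stop_score(cross, seqx, w, "met")$total, 2L)
})

test_that("membrane affinity classifies categories and Kd values", {
  expect_equal(classify_mai(c("nanomolar", "micromolar", "none")),
               c("S", "W", "N"))
  expect_equal(classify_mai(c(0.005, 5, 0.9999, 1)), c("S", "W", "S", "W"))
  expect_error(classify_mai(-2), "negative")
  expect_error(classify_mai("strongish"), "unknown affinity")
})
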