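test_that("spectrum configuration enforces probability and length invariants", {
  expect_error(indel_spectrum(p_deletion = 0.5, p_insertion = 0.5,
                              p_compound = 0.5), "is not TRUE")
  sp <- indel_spectrum()
  expect_equal(sp$p_deletion + sp$p_insertion + sp$p_compound, 1)
})

test_that("degenerate editing fractions produce the expected populations", {
  set.seed(51)
  locus <- make_random_locus(600)
  pop0 <- simulate_population(locus, 300L, 0, seed = 1L)
  expect_identical(length(pop0$templates), 1L)
  expect_identical(pop0$templates[[1]]$seq, locus$seq)
  expect_equal(pop0$templates[[1]]$weight, 1)
  pop1 <- simulate_population(locus, 300L, 1, n_distinct_edits = 1L,
                              seed = 2L)
  expect_identical(length(pop1$templates), 1L)
  truth <- pop1$templates[[1]]$truth
  # the single edited template is recovered exactly by the indel caller
  call <- call_indel(pop1$templates[[1]]$seq, locus, check_identity = FALSE)
  expect_identical(call$net_change, truth$net_change)
  expect_identical(call$frame_class, truth$frame_class)
})

test_that("population weights are positive, sum to one, and edits stay near the cut", {
  set.seed(52)
  locus <- make_random_locus(600)
  sp <- indel_spectrum(placement_jitter = 5L)
  for (seed in 1:5) {
    pop <- simulate_population(locus, 300L, 0.7, n_distinct_edits = 5L,
                               spectrum = sp, seed = seed)
    w <- vapply(pop$templates, `[[`, numeric(1), "weight")
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    for (t in pop$templates) {
      if (is.null(t$truth)) next
      mid <- (t$truth$del_start + t$truth$del_end) / 2
      expect_true(abs(mid - 300) <= sp$placement_jitter + 0.5)
    }
  }
})

test_that("the realized default spectrum matches its qualitative design over 10000 draws", {
  set.seed(53)
  locus <- make_random_locus(600)
  sp <- indel_spectrum(p_large_del = 0.01)
  dels <- integer(0); inss <- integer(0); n_compound <- 0L
  for (seed in 1:100) {
    pop <- simulate_population(locus, 300L, 1, n_distinct_edits = 100L,
                               spectrum = sp, seed = seed)
    for (t in pop$templates) {
      dlen <- t$truth$del_end - t$truth$del_start
      ilen <- nchar(t$truth$ins_seq)
      if (dlen > 0) dels <- c(dels, dlen)
      if (ilen > 0) inss <- c(inss, ilen)
      if (dlen > 0 && ilen > 0) n_compound <- n_compound + 1L
    }
  }
  expect_gt(mean(dels < 20), 0.5)       # small deletions dominate
  expect_gt(sum(dels > 100), 0)         # rare large deletions occur
  expect_gt(length(inss), 0)            # insertions occur
  expect_gt(n_compound, 0)              # simultaneous del+ins occur
})

test_that("a pure-WT population renders a perfectly clean trace", {
  set.seed(54)
  locus <- make_random_locus(600)
  pop <- simulate_population(locus, 300L, 0, seed = 3L)
  tr <- render_mixture_trace(pop, 0L, 400L, noise_rate = 0, seed = 3L)
  expect_identical(paste(tr$calls$primary, collapse = ""),
                   substr(locus$seq, 1, 400))
  expect_true(all(tr$calls$secondary == "-"))
  wt <- trace_read("wt", strsplit(substr(locus$seq, 1, 400), "")[[1]])
  prof <- compute_fidelity_profile(tr, wt)
  expect_true(all(prof$table$score == 1))
})

test_that("a 50/50 single-deletion mixture is hand-computable on a toy locus", {
  # 30 nt toy: WT and a 1-bp deletion at 0-based position 14
  wt_seq <- "ATGAAACCCGGGTTTACGTACGGATCCGTA"
  locus <- reference_locus("mini", wt_seq, cds_start = 0L,
                           cds_frame_len = 30L)
  del <- paste0(substr(wt_seq, 1, 14), substr(wt_seq, 16, 30))
  truth <- mosaicedit:::.indel_call("mini", 14L, 15L, "")
  pop <- structure(
    list(locus_id = "mini", cut_site = 15L, editing_fraction = 0.5,
         seed = 1L,
         templates = list(list(seq = wt_seq, weight = 0.5, truth = NULL),
                          list(seq = del, weight = 0.5, truth = truth))),
    class = "mosaic_population")
  tr <- render_mixture_trace(pop, 0L, 29L, ambiguity_ratio = 0.85,
                             noise_rate = 0, seed = 1L)
  wt_chars <- strsplit(wt_seq, "")[[1]]
  del_chars <- strsplit(del, "")[[1]]
  for (j in 1:29) {
    a <- wt_chars[j]; b <- del_chars[j]
    if (a == b) {
      expect_identical(tr$calls$primary[j], a)
      expect_identical(tr$calls$secondary[j], "-")
    } else {
      # equal weights: two-base IUPAC primary at every divergent position
      expect_setequal(expand_iupac(tr$calls$primary[j]), c(a, b))
    }
  }
  # upstream of the edit every call is clean
  expect_identical(paste(tr$calls$primary[1:14], collapse = ""),
                   substr(wt_seq, 1, 14))
})

test_that("a forced near-tie substitution yields the two-base IUPAC primary", {
  wt_seq <- paste0("ATG", strrep("ACGT", 7), "C")
  sub <- wt_seq
  substr(sub, 10, 10) <- "T"   # single divergent position
  pop <- structure(
    list(locus_id = "mini", cut_site = 10L, editing_fraction = 0.5,
         seed = 1L,
         templates = list(list(seq = wt_seq, weight = 0.5, truth = NULL),
                          list(seq = sub, weight = 0.5, truth = NULL))),
    class = "mosaic_population")
  tr <- render_mixture_trace(pop, 0L, 32L, ambiguity_ratio = 0.9,
                             seed = 1L)
  expect_setequal(expand_iupac(tr$calls$primary[10]),
                  c(substr(wt_seq, 10, 10), "T"))
})

test_that("register logic: a net -k deletion reads reference position p + k downstream", {
  set.seed(55)
  locus <- make_random_locus(600)
  k <- 7L
  del <- paste0(substr(locus$seq, 1, 300), substr(locus$seq, 308, 600))
  truth <- mosaicedit:::.indel_call(locus$id, 300L, 307L, "")
  pop <- structure(
    list(locus_id = locus$id, cut_site = 303L, editing_fraction = 1,
         seed = 1L,
         templates = list(list(seq = del, weight = 1, truth = truth))),
    class = "mosaic_population")
  tr <- render_mixture_trace(pop, 0L, 500L, seed = 1L)
  ref_chars <- strsplit(locus$seq, "")[[1]]
  for (p in sample(320:480, 20)) {
    expect_identical(tr$calls$primary[p], ref_chars[p + k])
  }
})

test_that("clone sampling follows template weights and is seed-deterministic", {
  set.seed(56)
  locus <- make_random_locus(600)
  pop <- simulate_population(locus, 300L, 0.5, n_distinct_edits = 3L,
                             seed = 9L)
  clones <- sample_clones(pop, 100L, seed = 9L)
  n_wt <- sum(clones$is_wt)
  # editing fraction 0.5: WT count within the binomial 99% interval
  expect_true(n_wt >= qbinom(0.005, 100, 0.5) &&
                n_wt <= qbinom(0.995, 100, 0.5))
  expect_identical(sample_clones(pop, 100L, seed = 9L), clones)
  expect_false(identical(sample_clones(pop, 100L, seed = 10L)$seq,
                         clones$seq))
  expect_identical(nrow(sample_clones(pop, 1L, seed = 1L)), 1L)
})

test_that("identical seeds give byte-identical artifacts, different seeds differ", {
  set.seed(57)
  locus <- make_random_locus(600)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  run_simulation(locus, 300L, 0.6, d1, seed = 5L, n_clones = 10L)
  run_simulation(locus, 300L, 0.6, d2, seed = 5L, n_clones = 10L)
  run_simulation(locus, 300L, 0.6, d3, seed = 6L, n_clones = 10L)
  for (f in c("sample_trace.csv", "wt_trace.csv", "clones.fasta",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "truth.json")),
                         readLines(file.path(d3, "truth.json"))))
})

test_that("simulation does not perturb the caller's RNG stream", {
  locus <- make_random_locus(600)
  set.seed(58)
  before <- .Random.seed
  invisible(simulate_population(locus, 300L, 0.5, seed = 99L))
  expect_identical(.Random.seed, before)
})
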