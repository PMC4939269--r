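test_that("in-silico digest finds the first MspI site from the labelled end", {
  # only CCGG begins at position 162 -> T-RF 162 bp (cut after base 162)
  s <- paste0(strrep("AT", 80), "G", "CCGG", strrep("TA", 60))
  stopifnot(regexpr("CCGG", s, fixed = TRUE) == 162)
  res <- insilico_digest(c(rec = s))
  expect_equal(res$trf_bp, 162)
  expect_equal(res$flag, "")

  # no site: full length, flagged
  res2 <- insilico_digest(c(rec = strrep("AT", 100)))
  expect_equal(res2$trf_bp, 200)
  expect_equal(res2$flag, "undigested")
})

test_that("digest agrees with a brute-force scanner on random sequences", {
  set.seed(101)
  for (i in 1:1000) {
    s <- random_dna(sample(30:120, 1))
    want <- oracle_trf(s)
    got <- insilico_digest(setNames(s, "r"))
    if (is.na(want)) {
      expect_equal(got$flag, "undigested")
      expect_equal(got$trf_bp, nchar(s))
    } else {
      expect_equal(got$trf_bp, want)
    }
  }
})

test_that("site placements at every position of a toy sequence are handled", {
  # plant a single CCGG at each position of a 50-bp site-free backbone
  backbone <- "ATTATAATTAATATTATAATATTAATTATAATATTAATTATAATATTAAT"
  for (pos in 1:(nchar(backbone) - 3)) {
    s <- paste0(substr(backbone, 1, pos - 1), "CCGG",
                substr(backbone, pos + 4, nchar(backbone)))
    got <- insilico_digest(setNames(s, "t"))$trf_bp
    expect_equal(got, oracle_trf(s))
    expect_equal(got, pos)    # (site_start - 1) + cut offset 1
  }
})

test_that("the labelled primer anchors the fragment, degenerately matched", {
  # primer with M (A/C) found internally; T-RF counts from the anchor
  tail <- "AATTAATTAATTCCGGAATT"                 # CCGG at 13 after anchor
  s <- paste0("GGGGG", "AGAGTTTGATCCTGGCTCAG", tail)
  res <- insilico_digest(c(x = s), primer = BA27F)
  expect_equal(res$trf_bp, 20 + 12 + 1)          # primer + 12 bases + offset

  expect_warning(
    out <- insilico_digest(c(x = "ATATATCCGGATAT", y = s), primer = BA27F),
    "primer not found")
  expect_equal(nrow(out), 1)                     # unanchorable record skipped
  expect_equal(out$id, "y")
})

test_that("the synthetic cable-bacteria amplicons predict a 162 bp T-RF", {
  res <- insilico_digest(fixture_fasta(), primer = BA27F)
  cable <- res[grepl("cable", res$id), ]
  expect_true(all(cable$trf_bp == 162))
  expect_true(all(res$trf_bp[grepl("other", res$id)] == 502))
})

test_that("fragment clustering is single-linkage at the bp threshold", {
  pt <- peak_table("a", c(159.0, 160.4, 163.0), c(10, 20, 30))
  cl <- cluster_fragments(pt, 2)
  expect_equal(cl$cluster, c(1, 1, 2))            # gaps 1.4 | 2.6
  cent <- attr(cl, "centroids")
  expect_equal(cent[["1"]], round((159 * 10 + 160.4 * 20) / 30, 1))
  expect_equal(cent[["2"]], 163.0)

  single <- cluster_fragments(peak_table("a", 101.3, 5))
  expect_equal(attr(single, "centroids")[["1"]], 101.3)

  # chaining: consecutive gaps <= 2 merge even though the span exceeds 2
  chain <- cluster_fragments(peak_table("a", c(100, 101.9, 103.8), c(1, 1, 1)))
  expect_equal(chain$cluster, c(1, 1, 1))

  empty <- cluster_fragments(peak_table(character(0), numeric(0), numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("clustering is permutation-invariant and idempotent", {
  set.seed(202)
  for (i in 1:20) {
    sizes <- sort(runif(sample(3:15, 1), 80, 600))
    pt <- peak_table("a", sizes, runif(length(sizes), 1, 100))
    cl <- cluster_fragments(pt, 2)
    perm <- sample(nrow(pt))
    cl_p <- cluster_fragments(pt[perm, ], 2)
    expect_equal(cl_p$cluster[order(perm)], cl$cluster)
    # single-linkage property: within a cluster every member has a
    # neighbour within the threshold
    for (k in unique(cl$cluster)) {
      s <- sort(pt$size_bp[cl$cluster == k])
      if (length(s) > 1) expect_true(all(diff(s) <= 2))
    }
    # gaps between adjacent clusters exceed the threshold
    cent_sizes <- split(pt$size_bp, cl$cluster)
    bounds <- sapply(cent_sizes, range)
    if (ncol(bounds) > 1) {
      o <- order(bounds[1, ])
      expect_true(all(bounds[1, o][-1] - bounds[2, o][-ncol(bounds)] > 2))
    }
  }
})

test_that("normalization yields per-replicate relative abundances summing to 1", {
  pt <- peak_table(c("a", "a", "b", "b", "b"), c(159, 502, 159, 163, 502),
                   c(40, 60, 10, 10, 20))
  norm <- normalize_fingerprint(pt)
  expect_equal(norm$height[1:2], c(0.40, 0.60))
  sums <- tapply(norm$height, norm$replicate_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  expect_equal(normalize_fingerprint(peak_table("a", 100, 5))$height, 1)
  expect_error(normalize_fingerprint(peak_table("a", 100, 0)), "a")
})

test_that("replicate summaries use zero-fill means and sample s.d.", {
  reps <- lapply(1:3, function(i)
    peak_table(paste0("r", i), c(159, 502), c(c(10, 20, 30)[i],
                                              c(90, 80, 70)[i])))
  sm <- summarize_replicates(reps, 2)
  i159 <- which(sm$centroid_bp < 200)
  expect_equal(sm$mean_abundance[i159], mean(c(0.10, 0.20, 0.30)))
  expect_equal(sm$sd_abundance[i159], sd(c(0.10, 0.20, 0.30)))

  # identical triplicates: zero s.d. everywhere
  same <- lapply(1:3, function(i) peak_table(paste0("r", i),
                                             c(159, 477), c(40, 60)))
  expect_true(all(summarize_replicates(same)$sd_abundance < 1e-12))

  # cluster present in one replicate of three at 0.30: zero-filled mean 0.10
  mixed <- list(peak_table("r1", c(100, 300), c(70, 30)),
                peak_table("r2", 100, 50),
                peak_table("r3", 100, 50))
  sm2 <- summarize_replicates(mixed, 2)
  i300 <- which(sm2$centroid_bp == 300)
  expect_equal(sm2$mean_abundance[i300], 0.1)
})
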