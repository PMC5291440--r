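# Random-substitution profiling and information content.

test_that("a constant classifier yields a flat profile at baseline 1", {
  proms <- sequence_records(sprintf("p%d", 1:20),
                            random_dna(20, 60, seed = 1),
                            label = "promoter", tss_index = 41)
  prof <- substitution_profile(function(s) rep(TRUE, length(s)), proms,
                               window_length = 6, replicates = 3, seed = 1)
  expect_equal(prof$baseline_sensitivity, 1)
  expect_true(all(prof$sensitivity == 1))
  expect_length(prof$sensitivity, 60 - 6 + 1)
})

test_that("profile dips exactly over the span a rule-based oracle uses", {
  # oracle: promoter iff TATAAA occupies 1-based positions 156..161
  seqs <- random_dna(40, 251, seed = 2)
  substr(seqs, 156, 161) <- "TATAAA"
  proms <- sequence_records(sprintf("p%d", 1:40), seqs,
                            label = "promoter", tss_index = 201)
  oracle <- positional_match_classifier("TATAAA", 156)
  prof <- substitution_profile(oracle, proms, window_length = 6,
                               replicates = 4, seed = 3)
  expect_length(prof$sensitivity, 251 - 6 + 1)
  overlap <- prof$window_starts >= 151 & prof$window_starts <= 161
  # an overlapping window survives only if the random replacement restores
  # all k overlapped motif bases: expected sensitivity 4^-k
  k <- vapply(prof$window_starts[overlap], function(s)
    length(intersect(s:(s + 5), 156:161)), integer(1))
  expect_true(all(prof$sensitivity[overlap] <= 4^(-k) + 0.12))
  expect_true(all(prof$sensitivity[!overlap] == 1))
  expect_equal(prof$baseline_sensitivity, 1)

  # minima reporting covers the union of implicated windows
  iv <- profile_minima(prof, drop_fraction = 0.5)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 151)
  expect_equal(iv$end, 166)      # last implicated start 161 + 6 - 1
  expect_equal(iv$tss_start, 151 - 201)
  expect_equal(iv$tss_end, 166 - 201)
})

test_that("two distant planted elements give two disjoint intervals", {
  seqs <- random_dna(40, 251, seed = 4)
  substr(seqs, 168, 174) <- "GGCGCGG"
  substr(seqs, 199, 201) <- "TCA"
  proms <- sequence_records(sprintf("p%d", 1:40), seqs,
                            label = "promoter", tss_index = 201)
  oracle <- function(s)
    substr(s, 168, 174) == "GGCGCGG" & substr(s, 199, 201) == "TCA"
  prof <- substitution_profile(oracle, proms, window_length = 6,
                               replicates = 4, seed = 5)
  iv <- profile_minima(prof, drop_fraction = 0.5)
  expect_equal(nrow(iv), 2)
  expect_lt(iv$end[1], iv$start[2])
})

test_that("flat profiles produce no intervals; zero baseline errors", {
  proms <- sequence_records("p1", strrep("ACGT", 10),
                            label = "promoter")
  prof <- substitution_profile(function(s) TRUE, proms,
                               window_length = 4, replicates = 2, seed = 1)
  expect_equal(nrow(profile_minima(prof)), 0)
  prof0 <- substitution_profile(function(s) FALSE, proms,
                                window_length = 4, replicates = 2,
                                seed = 1)
  expect_error(profile_minima(prof0), class = "promcnn_data_error")
})

test_that("profiles are deterministic given the seed", {
  proms <- sequence_records(sprintf("p%d", 1:10),
                            random_dna(10, 40, seed = 6),
                            label = "promoter")
  oracle <- function(s) substr(s, 10, 12) == "AAA"
  p1 <- substitution_profile(oracle, proms, 5, replicates = 3, seed = 11)
  p2 <- substitution_profile(oracle, proms, 5, replicates = 3, seed = 11)
  expect_identical(p1$sensitivity, p2$sensitivity)
})

test_that("incremental and full profiling paths agree exactly", {
  proms <- sequence_records(sprintf("p%d", 1:20),
                            random_dna(20, 81, seed = 20),
                            label = "promoter", tss_index = 61)
  # pooled, unpooled and global-pool geometries all reuse the base
  # forward pass differently; the profiles must not depend on the path
  for (ly in list(conv_layer(6, 7, 4), conv_layer(4, 9, 0),
                  conv_layer(4, 9, 70))) {
    m <- build_model(model_spec(81, ly, dense_units = 8), seed = 21)
    m$output$W[] <- promcnn:::with_seed(22, rnorm(16, sd = 0.4))
    pf <- substitution_profile(m, proms, 6, replicates = 3, seed = 23,
                               method = "full")
    pi <- substitution_profile(m, proms, 6, replicates = 3, seed = 23,
                               method = "incremental")
    expect_identical(pf$sensitivity, pi$sensitivity)
    expect_identical(pf$baseline_sensitivity, pi$baseline_sensitivity)
  }
})

test_that("random damage never helps a well-trained model beyond noise", {
  corpus <- generate_corpus(corpus_spec(
    120, 120, window_length = 81, tss_index = 61,
    motifs = list(motif_minus10(strength = 1)), seed = 24))
  sp <- split_dataset(corpus, seed = 24)
  fit <- train(parse_architecture("8, 9, 4", 81, dense_units = 16), sp,
               train_config(max_epochs = 15, patience = 5, seed = 24))
  proms <- rbind(sp$test, sp$validation)
  proms <- proms[proms$label == "promoter", ]
  prof <- substitution_profile(fit$model, proms, 6, replicates = 8,
                               seed = 25)
  # one-sided: no window may exceed baseline by more than 3 combined
  # standard errors (replicate spread + binomial noise of the baseline
  # estimate itself, since both are estimates on the same promoters)
  p <- prof$baseline_sensitivity
  se_base <- sqrt(p * (1 - p) / prof$n_promoters)
  se_rep <- ifelse(is.na(prof$se), 0, prof$se)
  expect_true(all(prof$sensitivity <= p + 3 * (se_base + se_rep)))
})

test_that("the argmin window overlaps the planted motif across seeds", {
  # bacterial-convention corpora keep this cheap: 81-nt windows, -10 box
  # (consensus TATAAT) planted at TSS-relative -10 = 1-based 51..56
  for (seed in 1:5) {
    corpus <- generate_corpus(corpus_spec(
      300, 300, window_length = 81, tss_index = 61,
      motifs = list(motif_minus10(strength = 1)), seed = seed))
    sp <- split_dataset(corpus, seed = seed)
    fit <- train(parse_architecture("16, 9, 4", 81, dense_units = 16), sp,
                 train_config(max_epochs = 20, patience = 6, seed = seed))
    rep <- evaluate(fit$model, sp$test)
    expect_gte(rep$AC, 0.95)
    proms <- sp$test[sp$test$label == "promoter", ]
    prof <- substitution_profile(fit$model, proms, 6, replicates = 5,
                                 seed = seed)
    amin <- prof$window_starts[which.min(prof$sensitivity)]
    expect_true(length(intersect(amin:(amin + 5), 51:56)) > 0,
                info = paste("seed", seed))
  }
})

test_that("window/precondition violations raise data errors", {
  proms <- sequence_records("p1", "ACGTACGT", label = "promoter")
  expect_error(substitution_profile(function(s) TRUE, proms,
                                    window_length = 9),
               class = "promcnn_data_error")
  expect_error(substitution_profile(function(s) TRUE, proms[0, ]),
               class = "promcnn_data_error")
})

test_that("information content matches the closed-form column cases", {
  ip_inv <- information_profile(c("T", "T", "T", "T"))
  expect_equal(ip_inv$ic, 2)
  ip_unif <- information_profile(c("A", "C", "G", "T"))
  expect_equal(ip_unif$ic, 0)
  ip_half <- information_profile(c("A", "A", "T", "T"))
  expect_equal(ip_half$ic, 1)   # 2 - H(0.5, 0.5)
  # N bases are excluded from the counts
  ip_n <- information_profile(c("A", "A", "N", "N"))
  expect_equal(ip_n$ic, 2)
})

test_that("small-sample correction subtracts 3/(2 ln2 n)", {
  x <- c("A", "A", "T", "T")
  raw <- information_profile(x)$ic
  corr <- information_profile(x, correction = TRUE)$ic
  expect_equal(raw - corr, 3 / (2 * log(2) * 4))
})

test_that("IC is bounded in [0, 2] and peaks localize the planted motif", {
  corpus <- tiny_separable_corpus(300, seed = 13, strength = 0.9)
  proms <- corpus[corpus$label == "promoter", ]
  ip <- information_profile(proms)
  expect_true(all(ip$ic >= 0 & ip$ic <= 2 + 1e-12))
  hot <- ip$position[ip$ic >= 1]
  expect_true(all(hot >= 171 & hot <= 178))
  expect_equal(ip$tss_relative[ip$position == 201], 0)
})

test_that("replicate averaging narrows the spread of profile points", {
  # noisy oracle: ignores sequence, fires with p = 0.5 -> per-window mean
  # has sd 0.5/sqrt(n*replicates); check the 1/replicates variance law
  proms <- sequence_records(sprintf("p%d", 1:30),
                            random_dna(30, 20, seed = 14),
                            label = "promoter")
  noisy <- function(s) runif(length(s)) < 0.5
  spread <- vapply(c(1, 16), function(reps) {
    p <- substitution_profile(noisy, proms, 4, replicates = reps,
                              seed = 15)
    sd(p$sensitivity)
  }, numeric(1))
  expect_gt(spread[1] / spread[2], 2)   # expect ~4x for 16x replicates
})

test_that("profile and logo tables serialize with convention headers", {
  proms <- sequence_records(sprintf("p%d", 1:5),
                            random_dna(5, 30, seed = 16),
                            label = "promoter", tss_index = 21)
  prof <- substitution_profile(function(s) TRUE, proms, 6,
                               replicates = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  first <- readLines(path, n = 1)
  expect_match(first, "^# promcnn substitution profile")
  expect_match(first, "1-based start")
  tab <- read.table(path, sep = "\t")
  expect_equal(nrow(tab), 25)
  expect_equal(tab$V2, tab$V1 - 21)

  ip <- information_profile(proms)
  lpath <- withr::local_tempfile(fileext = ".tsv")
  write_information_profile(ip, lpath)
  ltab <- read.table(lpath, sep = "\t")
  expect_equal(nrow(ltab), 30)
  expect_equal(rowSums(ltab[, 3:6]), rep(1, 30))
})
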