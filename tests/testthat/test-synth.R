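test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 11, n_genes = 8)
  expect_identical(generate_raw_variants(cfg), generate_raw_variants(cfg))
  expect_identical(generate_annotated_variants(cfg, 50, 50),
                   generate_annotated_variants(cfg, 50, 50))
  s1 <- generate_sequences(cfg, 4, 30, 60)
  s2 <- generate_sequences(cfg, 4, 30, 60)
  expect_identical(as.character(s1), as.character(s2))
  # byte-identical FASTA text
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(s1, f1); write_fasta(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("raw tables respect count arithmetic and record validity", {
  cfg <- generator_config(seed = 2, n_genes = 10, variants_per_gene = c(5, 5))
  raw <- generate_raw_variants(cfg)
  expect_equal(nrow(raw), 50)
  expect_true(all(raw$wt_aa %in% AA_CANONICAL))
  expect_true(all(raw$mut_aa %in% AA_CANONICAL))
  expect_true(all(raw$wt_aa != raw$mut_aa))
  expect_true(all(raw$position >= 1))
  expect_true(all(raw$clin_sig %in% c("benign", "likely_benign", "pathogenic",
                                      "likely_pathogenic", "vus", "conflicting")))
  expect_true(all(raw$allele_freq >= 0 & raw$allele_freq <= 1))
  expect_true(all(raw$rsa >= 0 & raw$rsa <= 1))
})

test_that("an all-VUS mix leaves no gene with a definitive fraction above zero", {
  cfg <- generator_config(seed = 3, n_genes = 6,
                          class_mix = c(vus = 1))
  raw <- generate_raw_variants(cfg)
  expect_true(all(raw$clin_sig == "vus"))
  cur <- build_datasets(raw)
  expect_equal(nrow(cur$dataset1), 0)
  expect_equal(nrow(cur$dataset2), 0)
})

test_that("annotated tables honour requested class counts", {
  cfg <- generator_config(seed = 4)
  d <- generate_annotated_variants(cfg, 0, 5)
  expect_equal(nrow(d), 5)
  expect_true(all(d$label == 1))
  expect_true(all(d$clin_sig == "pathogenic"))
  d2 <- generate_annotated_variants(cfg, 7, 3)
  expect_equal(table(d2$label)[["0"]], 7)
  expect_equal(table(d2$label)[["1"]], 3)
})

test_that("label-conditional ddG means, sds and correlation are recovered", {
  cfg <- generator_config(seed = 5)
  n <- 4000
  d <- generate_annotated_variants(cfg, n, n)
  for (lab in 0:1) {
    p <- if (lab == 1) cfg$ddg_pathogenic else cfg$ddg_benign
    for (k in 1:3) {
      v <- d[[paste0("ddg_p", k)]][d$label == lab]
      expect_lt(abs(mean(v) - p$mean[k]), 3 * p$sd[k] / sqrt(n))
    }
    # within-label inter-predictor Pearson correlation near the configured value
    expect_lt(abs(cor(d$ddg_p1[d$label == lab], d$ddg_p2[d$label == lab]) -
                    cfg$ddg_correlation), 0.05)
    expect_lt(abs(cor(d$ddg_p2[d$label == lab], d$ddg_p3[d$label == lab]) -
                    cfg$ddg_correlation), 0.05)
  }
})

test_that("exchangeable labels give chance-level AUC", {
  cfg <- generator_config(seed = 6,
                          ddg_pathogenic = list(mean = -0.5, sd = 1),
                          ddg_benign = list(mean = -0.5, sd = 1),
                          ddg_correlation = 0)
  d <- generate_annotated_variants(cfg, 1000, 1000)
  expect_lt(abs(auc_concordance(d$ddg_p1, d$label) - 0.5), 0.05)
})

test_that("the closed-form AUC matches its Gaussian formula and limits", {
  same <- generator_config(ddg_pathogenic = list(mean = -1, sd = 1),
                           ddg_benign = list(mean = -1, sd = 1))
  expect_equal(analytic_auc(same), 0.5)
  cfg <- generator_config()  # pathogenic N(-1.5, 1.5^2), benign N(-0.3, 1)
  expect_equal(analytic_auc(cfg, "ddg_p1"), pnorm(1.2 / sqrt(3.25)))
  expect_equal(analytic_auc(cfg, "ddg_p1"), 0.7472, tolerance = 1e-4)
  sep <- generator_config(ddg_pathogenic = list(mean = -2, sd = 1e-9),
                          ddg_benign = list(mean = 0, sd = 1e-9))
  expect_equal(analytic_auc(sep), 1.0)
  expect_error(analytic_auc(cfg, "ddg_p9"), "unknown predictor")
})

test_that("sequence generation honours length range and residue bias", {
  cfg <- generator_config(seed = 7)
  s <- generate_sequences(cfg, 3, 10, 10)
  expect_length(s, 3)
  expect_true(all(Biostrings::width(s) == 10))
  gly <- generator_config(seed = 8, aa_bias = c(G = 1))
  sg <- generate_sequences(gly, 2, 12, 12)
  expect_true(all(strsplit(as.character(sg[[1]]), "")[[1]] == "G"))
  expect_error(generate_sequences(cfg, 2, 0, 10), "min_len")
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(generator_config(class_mix = c(benign = 0.5, vus = 0.4)),
               "class_mix")
  expect_error(generator_config(ddg_pathogenic = list(mean = -1, sd = 0)),
               "ddg_pathogenic")
  expect_error(generator_config(ddg_correlation = 1.2), "ddg_correlation")
  expect_error(generator_config(rsa_benign = c(-1, 2)), "rsa_benign")
  expect_error(generator_config(af_benign = c(0.5, 0.1)), "af_benign")
})
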