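# Synthetic-data generator. Emulates the statistical structure of a curated
# monogenic-disorder variant set: label-conditional ddG (pathogenic variants
# more destabilizing), label-conditional RSA (pathogenic more buried), three
# correlated ddG predictor columns, multi-variant genes mixing all ClinVar
# significance classes, and allele frequencies straddling the 0.01 filter.
# Everything is driven by one seed; each operation derives a fixed child seed
# (raw table: seed+1, annotated table: seed+2, sequences: seed+3) from R's
# default Mersenne-Twister stream, so identical configs give byte-identical
# output.

FUNCTIONAL_CLASSES <- c(
  "enzyme", "transport/translocation/cargo protein", "transcription regulation",
  "structural support", "scaffold protein", "receptor protein",
  "signaling protein", "regulatory protein", "DNA binding", "motor protein",
  "secretory protein", "adhesion protein", "chaperone", "membrane protein",
  "RNA binding", "antigen-antibody complex", "miscellaneous")

SIGNIFICANCE_CLASSES <- c("benign", "likely_benign", "pathogenic",
                          "likely_pathogenic", "vus", "conflicting")

.default_aa_bias <- local({
  w <- setNames(rep(1, 20), AA_CANONICAL)
  # Arg-heavy wild-type usage, with Gly/Ala/Leu/Ser next, mirroring the
  # residue-usage skew of curated disease-variant sets.
  w["R"] <- 4; w["G"] <- 2.5; w["A"] <- 2.2; w["L"] <- 2; w["S"] <- 2
  w
})

#' Configuration for the synthetic variant generator
#'
#' Defines the study conditions under which synthetic variant tables,
#' annotated \eqn{\Delta\Delta G}/RSA datasets and protein sequences are
#' drawn. \eqn{\Delta\Delta G} uses the convention negative = destabilizing
#' (kcal/mol). Three simulated predictor columns share a configurable
#' inter-predictor correlation via a common latent factor.
#'
#' @param seed Integer master seed; child seeds are derived by fixed offsets.
#' @param n_genes Number of genes in raw tables.
#' @param variants_per_gene Length-2 integer range of variants per gene.
#' @param class_mix Named proportions over the six significance classes;
#'   must sum to 1.
#' @param af_benign,af_pathogenic Length-2 allele-frequency ranges; draws are
#'   log-uniform within the range so both sides of the 0.01 filter occur.
#' @param ddg_pathogenic,ddg_benign Lists with `mean` and `sd` (each scalar
#'   or length 3, one value per simulated predictor), kcal/mol.
#' @param ddg_correlation Inter-predictor correlation in \[0,1\].
#' @param rsa_pathogenic,rsa_benign Length-2 Beta shape parameters for RSA.
#' @param aa_bias Named positive weights over the 20 residues for wild-type
#'   draws (default Arg-heavy), or NULL for uniform.
#'
#' @return Object of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 7)
#' analytic_auc(cfg, "ddg_p1")
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 50L,
                             variants_per_gene = c(2L, 40L),
                             class_mix = c(benign = 0.15, likely_benign = 0.10,
                                           pathogenic = 0.25, likely_pathogenic = 0.15,
                                           vus = 0.25, conflicting = 0.10),
                             af_benign = c(1e-4, 0.2),
                             af_pathogenic = c(1e-5, 0.05),
                             ddg_pathogenic = list(mean = -1.5, sd = 1.5),
                             ddg_benign = list(mean = -0.3, sd = 1.0),
                             ddg_correlation = 0.6,
                             rsa_pathogenic = c(2, 3.2),
                             rsa_benign = c(3, 2),
                             aa_bias = .default_aa_bias) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid generator_config field '%s': %s", field, msg),
                  call. = FALSE)
  }
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed", "must be a single integer")
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes", "must be >= 1")
  chk(is.numeric(variants_per_gene) && length(variants_per_gene) == 2 &&
        variants_per_gene[1] >= 1 && variants_per_gene[1] <= variants_per_gene[2],
      "variants_per_gene", "must be an increasing range of integers >= 1")
  chk(is.numeric(class_mix) && !is.null(names(class_mix)) &&
        setequal(names(class_mix), SIGNIFICANCE_CLASSES) || (
          all(names(class_mix) %in% SIGNIFICANCE_CLASSES) && length(class_mix) >= 1),
      "class_mix", "must be named by significance class")
  chk(all(class_mix >= 0) && abs(sum(class_mix) - 1) <= 1e-9,
      "class_mix", "proportions must be non-negative and sum to 1")
  full_mix <- setNames(numeric(length(SIGNIFICANCE_CLASSES)), SIGNIFICANCE_CLASSES)
  full_mix[names(class_mix)] <- class_mix
  for (f in c("af_benign", "af_pathogenic")) {
    v <- get(f)
    chk(is.numeric(v) && length(v) == 2 && all(v > 0) && all(v <= 1) && v[1] <= v[2],
        f, "must be an increasing range within (0, 1]")
  }
  norm_ddg <- function(d, field) {
    chk(is.list(d) && all(c("mean", "sd") %in% names(d)), field, "must be list(mean=, sd=)")
    m <- rep_len(as.numeric(d$mean), 3L)
    s <- rep_len(as.numeric(d$sd), 3L)
    chk(all(is.finite(m)), field, "means must be finite")
    chk(all(s > 0), field, "sds must be > 0")
    list(mean = m, sd = s)
  }
  ddg_pathogenic <- norm_ddg(ddg_pathogenic, "ddg_pathogenic")
  ddg_benign <- norm_ddg(ddg_benign, "ddg_benign")
  chk(is.numeric(ddg_correlation) && length(ddg_correlation) == 1 &&
        ddg_correlation >= 0 && ddg_correlation <= 1,
      "ddg_correlation", "must be in [0, 1]")
  for (f in c("rsa_pathogenic", "rsa_benign")) {
    v <- get(f)
    chk(is.numeric(v) && length(v) == 2 && all(v > 0), f, "must be two positive Beta shapes")
  }
  if (!is.null(aa_bias)) {
    chk(is.numeric(aa_bias) && all(names(aa_bias) %in% AA_CANONICAL) && all(aa_bias >= 0) &&
          sum(aa_bias) > 0, "aa_bias", "must be non-negative weights named by residue")
    w <- setNames(numeric(20), AA_CANONICAL)
    w[names(aa_bias)] <- aa_bias
    aa_bias <- w
  } else {
    aa_bias <- setNames(rep(1, 20), AA_CANONICAL)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 variants_per_gene = as.integer(variants_per_gene),
                 class_mix = full_mix, af_benign = af_benign,
                 af_pathogenic = af_pathogenic,
                 ddg_pathogenic = ddg_pathogenic, ddg_benign = ddg_benign,
                 ddg_correlation = ddg_correlation,
                 rsa_pathogenic = rsa_pathogenic, rsa_benign = rsa_benign,
                 aa_bias = aa_bias),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic variant generator configuration\n")
  cat(sprintf("  seed %d; %d genes with %d-%d variants each\n", x$seed, x$n_genes,
              x$variants_per_gene[1], x$variants_per_gene[2]))
  cat(sprintf("  ddG pathogenic mean %s sd %s; benign mean %s sd %s (kcal/mol, corr %.2f)\n",
              paste(x$ddg_pathogenic$mean, collapse = "/"),
              paste(x$ddg_pathogenic$sd, collapse = "/"),
              paste(x$ddg_benign$mean, collapse = "/"),
              paste(x$ddg_benign$sd, collapse = "/"), x$ddg_correlation))
  cat(sprintf("  RSA pathogenic Beta(%.2g, %.2g); benign Beta(%.2g, %.2g)\n",
              x$rsa_pathogenic[1], x$rsa_pathogenic[2],
              x$rsa_benign[1], x$rsa_benign[2]))
  invisible(x)
}

.log_unif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

# sample() treats a length-1 vector as 1:x; this keeps degenerate ranges safe
.sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(seq(lo, hi), n, replace = TRUE)
}

.sample_aa <- function(n, bias) sample(AA_CANONICAL, n, replace = TRUE, prob = bias)

.sample_mut <- function(wt) {
  vapply(wt, function(a) sample(setdiff(AA_CANONICAL, a), 1L), character(1),
         USE.NAMES = FALSE)
}

# Correlated ddG draws for one label via a shared latent factor:
# ddg_k = mu_k + sd_k * (sqrt(rho) Z0 + sqrt(1-rho) Zk), giving pairwise
# Pearson correlation rho and marginal N(mu_k, sd_k^2).
.draw_ddg <- function(n, params, rho) {
  z0 <- rnorm(n)
  out <- matrix(NA_real_, n, 3)
  for (k in 1:3) {
    out[, k] <- params$mean[k] +
      params$sd[k] * (sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n))
  }
  colnames(out) <- paste0("ddg_p", 1:3)
  out
}

.is_pathogenic_class <- function(cls) cls %in% c("pathogenic", "likely_pathogenic")
.is_benign_class <- function(cls) cls %in% c("benign", "likely_benign")

#' Generate a raw ClinVar-style variant table
#'
#' Draws `n_genes` genes with a per-gene number of variants uniform in
#' `variants_per_gene`. Each gene's significance mix is tilted between the
#' configured `class_mix` and a VUS-only mix so that the per-gene 10% rule
#' of the curation stage has both outcomes represented. All records,
#' including VUS and conflicting ones, carry \eqn{\Delta\Delta G} and RSA
#' values (VUS/conflicting draw from an even latent mixture of the two label
#' distributions); the curation stage is responsible for dropping them.
#'
#' @param config A [generator_config()].
#' @return Data frame with columns gene, protein_id, position, wt_aa, mut_aa,
#'   clin_sig, allele_freq, ddg_p1..ddg_p3, rsa, functional_class, label
#'   (1 pathogenic-side, 0 benign-side, NA otherwise).
#' @export
generate_raw_variants <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 1L, {
    vus_mix <- setNames(numeric(6), SIGNIFICANCE_CLASSES)
    vus_mix["vus"] <- 1
    pieces <- vector("list", config$n_genes)
    fclass_w <- c(6, 3, 2.5, rep(1, length(FUNCTIONAL_CLASSES) - 3))  # enzyme-dominated
    for (g in seq_len(config$n_genes)) {
      n_i <- .sample_range(config$variants_per_gene[1], config$variants_per_gene[2], 1L)
      u <- runif(1)
      mix <- u * config$class_mix + (1 - u) * vus_mix
      cls <- sample(SIGNIFICANCE_CLASSES, n_i, replace = TRUE, prob = mix)
      wt <- .sample_aa(n_i, config$aa_bias)
      af <- numeric(n_i)
      af[.is_benign_class(cls)] <- .log_unif(sum(.is_benign_class(cls)), config$af_benign)
      af[.is_pathogenic_class(cls)] <- .log_unif(sum(.is_pathogenic_class(cls)),
                                                 config$af_pathogenic)
      other <- !(.is_benign_class(cls) | .is_pathogenic_class(cls))
      af[other] <- .log_unif(sum(other), c(config$af_pathogenic[1], config$af_benign[2]))
      # latent truth drives ddG/RSA: observed label for definitive/likely
      # classes, a fair coin for vus/conflicting
      latent <- ifelse(.is_pathogenic_class(cls), 1L,
                       ifelse(.is_benign_class(cls), 0L,
                              as.integer(runif(n_i) < 0.5)))
      ddg <- matrix(NA_real_, n_i, 3)
      rsa <- numeric(n_i)
      for (lab in 0:1) {
        idx <- which(latent == lab)
        if (!length(idx)) next
        p <- if (lab == 1) config$ddg_pathogenic else config$ddg_benign
        b <- if (lab == 1) config$rsa_pathogenic else config$rsa_benign
        ddg[idx, ] <- .draw_ddg(length(idx), p, config$ddg_correlation)
        rsa[idx] <- rbeta(length(idx), b[1], b[2])
      }
      pieces[[g]] <- data.frame(
        gene = sprintf("GENE%04d", g),
        protein_id = sprintf("SYNP%04d", g),
        position = sample.int(1500L, n_i, replace = TRUE),
        wt_aa = wt,
        mut_aa = .sample_mut(wt),
        clin_sig = cls,
        allele_freq = af,
        ddg_p1 = ddg[, 1], ddg_p2 = ddg[, 2], ddg_p3 = ddg[, 3],
        rsa = rsa,
        functional_class = sample(FUNCTIONAL_CLASSES, n_i, replace = TRUE,
                                  prob = fclass_w / sum(fclass_w)),
        label = ifelse(.is_pathogenic_class(cls), 1L,
                       ifelse(.is_benign_class(cls), 0L, NA_integer_)),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, pieces)
  })
}

#' Generate an annotated two-class variant table
#'
#' Draws exactly `n_benign` benign and `n_pathogenic` pathogenic variants
#' with three correlated \eqn{\Delta\Delta G} columns from the label's
#' multivariate Gaussian and an RSA value from the label's Beta distribution.
#'
#' @param config A [generator_config()].
#' @param n_benign,n_pathogenic Non-negative row counts.
#' @return Data frame in the same schema as [generate_raw_variants()], with
#'   clin_sig in benign/pathogenic and label 0/1.
#' @export
generate_annotated_variants <- function(config, n_benign, n_pathogenic) {
  stopifnot(inherits(config, "generator_config"))
  if (n_benign < 0 || n_pathogenic < 0) {
    stop("n_benign and n_pathogenic must be >= 0", call. = FALSE)
  }
  with_seed(config$seed + 2L, {
    n <- n_benign + n_pathogenic
    label <- rep(c(0L, 1L), c(n_benign, n_pathogenic))
    ddg <- matrix(NA_real_, n, 3, dimnames = list(NULL, paste0("ddg_p", 1:3)))
    rsa <- numeric(n)
    for (lab in 0:1) {
      idx <- which(label == lab)
      if (!length(idx)) next
      p <- if (lab == 1) config$ddg_pathogenic else config$ddg_benign
      b <- if (lab == 1) config$rsa_pathogenic else config$rsa_benign
      ddg[idx, ] <- .draw_ddg(length(idx), p, config$ddg_correlation)
      rsa[idx] <- rbeta(length(idx), b[1], b[2])
    }
    wt <- .sample_aa(n, config$aa_bias)
    af <- numeric(n)
    af[label == 0] <- .log_unif(n_benign, config$af_benign)
    af[label == 1] <- .log_unif(n_pathogenic, config$af_pathogenic)
    out <- data.frame(
      gene = sprintf("GENE%04d", sample.int(max(config$n_genes, 1L), n, replace = TRUE)),
      protein_id = NA_character_,
      position = sample.int(1500L, n, replace = TRUE),
      wt_aa = wt,
      mut_aa = .sample_mut(wt),
      clin_sig = ifelse(label == 1, "pathogenic", "benign"),
      allele_freq = af,
      ddg_p1 = ddg[, 1], ddg_p2 = ddg[, 2], ddg_p3 = ddg[, 3],
      rsa = rsa,
      functional_class = sample(FUNCTIONAL_CLASSES, n, replace = TRUE),
      label = label,
      stringsAsFactors = FALSE)
    out$protein_id <- sub("GENE", "SYNP", out$gene)
    out
  })
}

#' Analytic AUC of one simulated predictor
#'
#' For the two-class Gaussian generator with pathogenicity score
#' \eqn{-\Delta\Delta G}, the population AUC has the closed form
#' \eqn{\Phi((\mu_b - \mu_p) / \sqrt{\sigma_b^2 + \sigma_p^2})}.
#'
#' @param config A [generator_config()] (Gaussian ddG parameters).
#' @param predictor One of "ddg_p1", "ddg_p2", "ddg_p3".
#' @return Probability that a random pathogenic variant is scored more
#'   pathogenic than a random benign one.
#' @export
analytic_auc <- function(config, predictor = "ddg_p1") {
  stopifnot(inherits(config, "generator_config"))
  k <- match(predictor, paste0("ddg_p", 1:3))
  if (is.na(k)) stop(sprintf("unknown predictor '%s'", predictor), call. = FALSE)
  mu_p <- config$ddg_pathogenic$mean[k]; sd_p <- config$ddg_pathogenic$sd[k]
  mu_b <- config$ddg_benign$mean[k]; sd_b <- config$ddg_benign$sd[k]
  pnorm((mu_b - mu_p) / sqrt(sd_b^2 + sd_p^2))
}

#' Generate synthetic protein sequences
#'
#' @param config A [generator_config()]; `aa_bias` weights the residues.
#' @param n Number of sequences.
#' @param min_len,max_len Length range (uniform), `1 <= min_len <= max_len`.
#' @return A [Biostrings::AAStringSet] named SYNSEQ0001, ...
#' @export
generate_sequences <- function(config, n, min_len, max_len) {
  stopifnot(inherits(config, "generator_config"))
  if (min_len < 1) stop("min_len must be >= 1", call. = FALSE)
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  with_seed(config$seed + 3L, {
    lens <- .sample_range(min_len, max_len, n)
    seqs <- vapply(lens, function(L) {
      paste(.sample_aa(L, config$aa_bias), collapse = "")
    }, character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- sprintf("SYNSEQ%04d", seq_len(n))
    out
  })
}
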