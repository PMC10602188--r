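# In-silico saturation mutagenesis: enumerate all 19 substitutions at every
# position of a protein, score each with a pluggable ddG scorer, and flag
# pathogenicity at a ddG cutoff (default -1.1 kcal/mol; score <= cutoff is
# flagged). The scorer contract: a function f(sequence, position, wt, mut)
# returning finite ddG values (kcal/mol, negative = destabilizing),
# deterministic for fixed input, and vectorized over position/wt/mut.

#' Enumerate all single-residue substitutions of a sequence
#'
#' @param sequence Character string (or AAString) of canonical residues.
#' @param skip_noncanonical Skip positions with non-canonical residues
#'   instead of erroring (default FALSE).
#' @return Data frame with columns position (1-based), wt_aa, mut_aa;
#'   exactly 19 rows per retained position, mutants in alphabetical order.
#' @export
enumerate_substitutions <- function(sequence, skip_noncanonical = FALSE) {
  seq_chr <- as.character(sequence)
  if (length(seq_chr) != 1 || nchar(seq_chr) == 0) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  res <- strsplit(seq_chr, "")[[1]]
  bad <- which(!(res %in% AA_CANONICAL))
  if (length(bad)) {
    if (!skip_noncanonical) {
      stop(sprintf("non-canonical residue '%s' at position %d", res[bad[1]], bad[1]),
           call. = FALSE)
    }
    keep <- setdiff(seq_along(res), bad)
  } else {
    keep <- seq_along(res)
  }
  out <- data.frame(position = rep(keep, each = 20L),
                    wt_aa = rep(res[keep], each = 20L),
                    mut_aa = rep(AA_CANONICAL, times = length(keep)),
                    stringsAsFactors = FALSE)
  out <- out[out$wt_aa != out$mut_aa, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deterministic synthetic ddG scorer
#'
#' Returns a scorer satisfying the scorer contract whose values are a fixed
#' integer-hash function of (position, wt, mut) and the seed, mapped to
#' \[-3.5, 1.5\] kcal/mol. Useful for exercising saturation scans without an
#' external predictor; the values carry no biophysical meaning.
#'
#' @param seed Integer mixed into the hash.
#' @return Function `(sequence, position, wt, mut) -> ddg`, vectorized.
#' @export
synthetic_scorer <- function(seed = 1) {
  seed <- as.numeric(seed)
  function(sequence, position, wt, mut) {
    wi <- match(wt, AA_CANONICAL)
    mi <- match(mut, AA_CANONICAL)
    if (any(is.na(wi)) || any(is.na(mi))) {
      stop("scorer received non-canonical residues", call. = FALSE)
    }
    # exact integer arithmetic in doubles (all terms << 2^53)
    h <- (1103515245 * (position * 20 + wi) + 12345 * mi + seed * 2654435) %% 100003
    -3.5 + 5 * h / 100002
  }
}

#' Saturation scan of one protein
#'
#' @param sequence Protein sequence (string or AAString), canonical residues.
#' @param scorer Scorer function per the contract above; default
#'   [synthetic_scorer()].
#' @param cutoff ddG pathogenicity cutoff in kcal/mol, default -1.1
#'   (flag iff ddg <= cutoff).
#' @param id Protein identifier recorded in the scan.
#' @param skip_noncanonical Skip non-canonical positions instead of erroring.
#' @return Object of class `saturation_scan`: list with protein_id, length,
#'   cutoff and `table` (position, wt_aa, mut_aa, ddg, pathogenic 0/1;
#'   19 rows per scanned position).
#' @export
saturation_scan <- function(sequence, scorer = synthetic_scorer(),
                            cutoff = -1.1, id = "protein",
                            skip_noncanonical = FALSE) {
  subs <- enumerate_substitutions(sequence, skip_noncanonical)
  ddg <- scorer(as.character(sequence), subs$position, subs$wt_aa, subs$mut_aa)
  if (length(ddg) != nrow(subs) || any(!is.finite(ddg))) {
    bad <- which(!is.finite(ddg))[1]
    stop(sprintf("scorer returned a non-finite ddG%s",
                 if (length(bad) && !is.na(bad))
                   sprintf(" for %s%d%s", subs$wt_aa[bad], subs$position[bad],
                           subs$mut_aa[bad]) else ""), call. = FALSE)
  }
  subs$ddg <- ddg
  subs$pathogenic <- as.integer(ddg <= cutoff)
  structure(list(protein_id = id, length = nchar(as.character(sequence)),
                 cutoff = cutoff, table = subs),
            class = "saturation_scan")
}

#' @export
print.saturation_scan <- function(x, ...) {
  cat(sprintf("Saturation scan of %s: L = %d, %d substitutions, %d flagged pathogenic (cutoff %.2f kcal/mol)\n",
              x$protein_id, x$length, nrow(x$table), sum(x$table$pathogenic),
              x$cutoff))
  invisible(x)
}

#' Totals over a list of saturation scans
#'
#' @param scans Non-empty list of `saturation_scan` objects.
#' @return List with total_mutations, total_pathogenic and fraction.
#' @export
summarize_scans <- function(scans) {
  if (inherits(scans, "saturation_scan")) scans <- list(scans)
  if (!length(scans)) stop("empty scan list", call. = FALSE)
  tot <- sum(vapply(scans, function(s) nrow(s$table), numeric(1)))
  path <- sum(vapply(scans, function(s) sum(s$table$pathogenic), numeric(1)))
  list(total_mutations = tot, total_pathogenic = path, fraction = path / tot)
}

#' Saturation-scan a FASTA file or sequence set
#'
#' Scans each record in turn and, when `out_tsv` is given, streams the rows
#' protein by protein so proteome-scale runs never hold all rows in memory.
#'
#' @param fasta Path to a FASTA file or a [Biostrings::AAStringSet].
#' @param scorer,cutoff,skip_noncanonical Passed to [saturation_scan()].
#' @param out_tsv Optional path; scan rows (protein_id, position, wt_aa,
#'   mut_aa, ddg, pathogenic) are appended per protein.
#' @param keep_tables Keep per-protein tables in the returned scans
#'   (default TRUE; set FALSE for large streamed runs).
#' @return Invisibly, list with `scans` (per-protein `saturation_scan`s,
#'   tables dropped when `keep_tables = FALSE`) and `summary` from
#'   [summarize_scans()].
#' @export
scan_fasta <- function(fasta, scorer = synthetic_scorer(), cutoff = -1.1,
                       out_tsv = NULL, skip_noncanonical = FALSE,
                       keep_tables = TRUE) {
  seqs <- if (inherits(fasta, "AAStringSet")) fasta else
    Biostrings::readAAStringSet(fasta)
  if (!length(seqs)) stop("no sequences to scan", call. = FALSE)
  ids <- if (is.null(names(seqs))) sprintf("seq%04d", seq_along(seqs)) else names(seqs)
  scans <- vector("list", length(seqs))
  total <- 0; flagged <- 0
  if (!is.null(out_tsv)) {
    con <- file(out_tsv, "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste(c("protein_id", "position", "wt_aa", "mut_aa", "ddg",
                       "pathogenic"), collapse = "\t"), con)
  }
  for (i in seq_along(seqs)) {
    s <- saturation_scan(as.character(seqs[[i]]), scorer, cutoff, ids[i],
                         skip_noncanonical)
    total <- total + nrow(s$table)
    flagged <- flagged + sum(s$table$pathogenic)
    if (!is.null(out_tsv)) {
      write.table(cbind(protein_id = ids[i], s$table), con, sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    if (!keep_tables) s$table <- NULL
    scans[[i]] <- s
  }
  out <- list(scans = scans,
              summary = list(total_mutations = total, total_pathogenic = flagged,
                             fraction = flagged / total))
  invisible(out)
}
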