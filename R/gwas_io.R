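# Reading, validating, writing GWAS summary-statistic tables, and
# harmonization of effect alleles across traits.

#' Canonical summary-statistic column names
#'
#' Per-SNP GWAS association tables use the columns `SNP` (identifier),
#' `CHR` (chromosome, stored as character so X/MT are admissible),
#' `BP` (1-based position), `EA`/`OA` (effect and other allele),
#' `EAF` (effect-allele frequency, may be `NA`), `BETA` (effect per copy of
#' the effect allele), `SE` (standard error), `P` (p-value) and `N`
#' (sample size).
#'
#' @format Character vector of the ten canonical column names.
#' @export
SUMMARY_STAT_COLUMNS <- c("SNP", "CHR", "BP", "EA", "OA",
                          "EAF", "BETA", "SE", "P", "N")

#' Construct a validated summary-statistic table
#'
#' @param df data.frame with the canonical columns (see
#'   [SUMMARY_STAT_COLUMNS]).
#' @param trait_label Character label for the trait the associations refer to.
#' @return A `summary_stat_table` (a data.frame with a `trait_label`
#'   attribute). Rows violating per-record invariants raise an error that
#'   lists the offending row numbers.
#' @export
summary_stat_table <- function(df, trait_label = "trait") {
  missing_cols <- setdiff(SUMMARY_STAT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    ts_error("twostepmr_format_error",
             sprintf("missing mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  df <- df[, SUMMARY_STAT_COLUMNS, drop = FALSE]
  df$SNP <- as.character(df$SNP)
  df$CHR <- as.character(df$CHR)
  df$EA <- toupper(as.character(df$EA))
  df$OA <- toupper(as.character(df$OA))
  for (col in c("BP", "EAF", "BETA", "SE", "P", "N")) {
    if (!is.numeric(df[[col]])) {
      orig <- df[[col]]
      conv <- suppressWarnings(as.numeric(as.character(orig)))
      bad <- which(is.na(conv) & !is.na(orig) & trimws(as.character(orig)) != "" &
                     !toupper(trimws(as.character(orig))) %in% c("NA", "NAN"))
      if (length(bad) > 0) {
        ts_error("twostepmr_format_error",
                 sprintf("column %s is not numeric at row(s): %s",
                         col, paste(utils::head(bad, 20), collapse = ", ")))
      }
      df[[col]] <- conv
    }
  }
  problems <- validate_summary_stat_rows(df)
  if (length(problems) > 0) {
    ts_error("twostepmr_data_error",
             paste0("invalid summary-statistic row(s):\n  ",
                    paste(utils::head(problems, 20), collapse = "\n  ")))
  }
  dup <- df$SNP[duplicated(df$SNP)]
  if (length(dup) > 0) {
    ts_error("twostepmr_data_error",
             sprintf("duplicate snp_id(s): %s",
                     paste(unique(utils::head(dup, 10)), collapse = ", ")))
  }
  rownames(df) <- NULL
  structure(df, trait_label = trait_label,
            class = c("summary_stat_table", "data.frame"))
}

# Per-record invariants; returns a character vector "row <i>: <reason>".
validate_summary_stat_rows <- function(df) {
  bases <- c("A", "C", "G", "T")
  msgs <- character(0)
  add <- function(rows, reason) {
    if (length(rows) > 0) {
      msgs <<- c(msgs, sprintf("row %d: %s", rows, reason))
    }
    invisible(NULL)
  }
  n <- nrow(df)
  if (n == 0) return(msgs)
  add(which(is.na(df$SNP) | df$SNP == ""), "empty snp_id")
  add(which(is.na(df$CHR) | df$CHR == ""), "empty chromosome")
  add(which(is.na(df$BP) | df$BP < 1 | df$BP != floor(df$BP)),
      "position must be a positive integer")
  add(which(!(df$EA %in% bases)), "effect_allele not one of A/C/G/T")
  add(which(!(df$OA %in% bases)), "other_allele not one of A/C/G/T")
  add(which(df$EA == df$OA), "effect_allele equals other_allele")
  add(which(!is.na(df$EAF) & (df$EAF <= 0 | df$EAF >= 1)),
      "eaf outside (0,1)")
  add(which(is.na(df$BETA) | !is.finite(df$BETA)), "beta missing/non-finite")
  add(which(is.na(df$SE) | df$SE <= 0), "se must be > 0")
  add(which(is.na(df$P) | df$P <= 0 | df$P > 1), "pvalue outside (0,1]")
  add(which(is.na(df$N) | df$N <= 0), "sample size must be positive")
  msgs[order(as.integer(sub("^row ([0-9]+):.*$", "\\1", msgs)))]
}

#' Trait label of a summary-statistic table
#' @param x summary_stat_table
#' @return character label
#' @export
trait_label <- function(x) attr(x, "trait_label") %||% "trait"

#' Read a GWAS summary-statistic file
#'
#' Reads a tab-separated table with the canonical header (see
#' [SUMMARY_STAT_COLUMNS]); `dialect` renames columns from other
#' conventions, e.g. `c(SNP = "rsid", BETA = "b")` maps the file's `rsid`
#' column onto `SNP`.
#'
#' @param path Path to a tab-separated file.
#' @param dialect Named character vector mapping canonical column names to
#'   the file's column names. Unmapped canonical names are taken verbatim.
#' @param trait_label Trait label; defaults to the file name.
#' @return A validated [summary_stat_table()].
#' @export
read_summary_stats <- function(path, dialect = NULL, trait_label = NULL) {
  if (!file.exists(path)) {
    ts_error("twostepmr_io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        ts_error("twostepmr_format_error",
                 sprintf("dialect maps %s to missing column '%s'", canon, src))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  summary_stat_table(raw, trait_label %||% basename(path))
}

#' Write a summary-statistic table
#'
#' Writes tab-separated text with the canonical header. Numeric fields are
#' written with 17 significant digits so that
#' `read_summary_stats(write_summary_stats(x))` round-trips doubles exactly.
#'
#' @param table A [summary_stat_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(table, path) {
  stopifnot(inherits(table, "summary_stat_table"))
  out <- as.data.frame(table)
  for (col in c("EAF", "BETA", "SE", "P", "N")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], digits = 17, format = "g"))
  }
  out$BP <- format(out$BP, scientific = FALSE, trim = TRUE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    ts_error("twostepmr_io_error",
             sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Low-level constructor for a harmonized SNP-effect set
#'
#' Exposure is always the first trait. All per-trait vectors are aligned to
#' `snp_id`.
#'
#' @param snp_id Character vector of SNP identifiers.
#' @param traits Character vector of trait labels, exposure first, outcome
#'   last.
#' @param beta,se Numeric matrices (`length(snp_id)` x `length(traits)`).
#' @param eaf,p,n Optional matrices of the same shape.
#' @param chrom,pos Optional per-SNP coordinates.
#' @param drop_log Optional data.frame with columns `SNP` and `action`
#'   recording per-SNP disposition.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(snp_id, traits, beta, se,
                           eaf = NULL, p = NULL, n = NULL,
                           chrom = NULL, pos = NULL, drop_log = NULL) {
  beta <- as.matrix(beta)
  se <- as.matrix(se)
  k <- length(snp_id)
  t <- length(traits)
  stopifnot(nrow(beta) == k, ncol(beta) == t,
            nrow(se) == k, ncol(se) == t, all(se > 0))
  colnames(beta) <- colnames(se) <- traits
  if (!is.null(eaf)) { eaf <- as.matrix(eaf); colnames(eaf) <- traits }
  if (!is.null(p)) { p <- as.matrix(p); colnames(p) <- traits }
  if (!is.null(n)) { n <- as.matrix(n); colnames(n) <- traits }
  structure(list(snp_id = as.character(snp_id), traits = traits,
                 beta = beta, se = se, eaf = eaf, p = p, n = n,
                 chrom = chrom, pos = pos,
                 drop_log = drop_log %||%
                   data.frame(SNP = as.character(snp_id),
                              action = rep("kept", k),
                              stringsAsFactors = FALSE)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %d SNPs x %d traits (%s)\n",
              length(x$snp_id), length(x$traits),
              paste(x$traits, collapse = " -> ")))
  tab <- table(x$drop_log$action)
  cat("  dispositions:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

n_snps <- function(h) length(h$snp_id)

#' Extract one trait of a harmonized set as a summary-statistic table
#'
#' @param h harmonized_set
#' @param trait Trait label or column index.
#' @return [summary_stat_table()] with the aligned records.
#' @export
hs_table <- function(h, trait) {
  j <- if (is.character(trait)) match(trait, h$traits) else trait
  stopifnot(!is.na(j), j >= 1, j <= length(h$traits))
  k <- n_snps(h)
  ea <- attr(h, "EA") %||% rep("A", k)
  oa <- attr(h, "OA") %||% rep("G", k)
  summary_stat_table(data.frame(
    SNP = h$snp_id,
    CHR = h$chrom %||% rep("1", k),
    BP = h$pos %||% seq_len(k),
    EA = ea, OA = oa,
    EAF = if (is.null(h$eaf)) rep(NA_real_, k) else h$eaf[, j],
    BETA = h$beta[, j], SE = h$se[, j],
    P = if (is.null(h$p)) pnorm_two(h$beta[, j] / h$se[, j]) else h$p[, j],
    N = if (is.null(h$n)) rep(1e5, k) else h$n[, j],
    stringsAsFactors = FALSE), trait_label = h$traits[j])
}

# Resolve one non-exposure record against the exposure's allele pair.
# Returns list(action, flip) where action in kept/flipped/dropped-*.
resolve_alleles <- function(ea_x, oa_x, eaf_x, ea_o, oa_o, eaf_o, limit) {
  if (is_palindromic_pair(ea_x, oa_x)) {
    same_pair <- (ea_o == ea_x && oa_o == oa_x) ||
      (ea_o == oa_x && oa_o == ea_x)
    if (!same_pair) return(list(action = "dropped-mismatch", flip = FALSE))
    # label alignment first: swapped labels imply a provisional flip
    label_flip <- (ea_o == oa_x)
    eaf_aligned <- if (label_flip) 1 - eaf_o else eaf_o
    if (is.na(eaf_x) || is.na(eaf_aligned)) {
      return(list(action = "dropped-palindromic", flip = FALSE))
    }
    side <- function(f) {
      if (f < limit) -1L else if (f > 1 - limit) 1L else 0L
    }
    sx <- side(eaf_x); so <- side(eaf_aligned)
    if (sx == 0L || so == 0L) {
      return(list(action = "dropped-palindromic", flip = FALSE))
    }
    strand_flip <- sx != so
    flip <- xor(label_flip, strand_flip)
    return(list(action = if (flip) "flipped" else "kept", flip = flip))
  }
  cea <- allele_complement(ea_x); coa <- allele_complement(oa_x)
  if ((ea_o == ea_x && oa_o == oa_x) || (ea_o == cea && oa_o == coa)) {
    return(list(action = "kept", flip = FALSE))
  }
  if ((ea_o == oa_x && oa_o == ea_x) || (ea_o == coa && oa_o == cea)) {
    return(list(action = "flipped", flip = TRUE))
  }
  list(action = "dropped-mismatch", flip = FALSE)
}

#' Harmonize effect alleles across traits
#'
#' Aligns every non-exposure table to the exposure's effect allele on the
#' intersection of SNP identifiers. Records whose effect/other alleles are
#' swapped relative to the exposure (on either strand) have their beta
#' negated and eaf replaced by 1 - eaf. Palindromic SNPs (A/T or G/C) are
#' kept with strand inferred from allele frequency when both frequencies
#' fall outside `[palindromic_eaf_limit, 1 - palindromic_eaf_limit]`
#' (same side: same strand; opposite sides: flipped), and dropped
#' otherwise. SNPs absent from any table, or with irreconcilable allele
#' pairs, are dropped with the reason recorded in `drop_log`.
#'
#' @param exposure [summary_stat_table()] defining the instrument direction.
#' @param others A single table or list of tables (mediators and/or
#'   outcome); the outcome is conventionally last.
#' @param palindromic_eaf_limit Frequency band half-limit for palindromic
#'   strand inference (default 0.42, common two-sample MR practice).
#' @return A [harmonized_set()] with traits `(exposure, others...)` and a
#'   `drop_log` covering every SNP in the union of inputs.
#' @export
harmonize <- function(exposure, others, palindromic_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "summary_stat_table"))
  if (inherits(others, "summary_stat_table")) others <- list(others)
  stopifnot(length(others) >= 1,
            all(vapply(others, inherits, TRUE, "summary_stat_table")),
            palindromic_eaf_limit > 0, palindromic_eaf_limit < 0.5)
  tabs <- c(list(exposure), others)
  labels <- vapply(tabs, trait_label, "")
  labels <- make.unique(labels)
  all_ids <- unique(unlist(lapply(tabs, function(t) t$SNP)))
  common <- exposure$SNP[exposure$SNP %in% Reduce(intersect,
                                                  lapply(tabs, `[[`, "SNP"))]
  action <- setNames(rep("dropped-missing", length(all_ids)), all_ids)

  idx <- lapply(tabs, function(t) match(common, t$SNP))
  k <- length(common)
  t_n <- length(tabs)
  beta <- se <- eaf <- pp <- nn <- matrix(NA_real_, k, t_n)
  keep <- rep(TRUE, k)
  flip_any <- rep(FALSE, k)
  for (i in seq_len(k)) {
    x <- exposure[idx[[1]][i], ]
    beta[i, 1] <- x$BETA; se[i, 1] <- x$SE
    eaf[i, 1] <- x$EAF; pp[i, 1] <- x$P; nn[i, 1] <- x$N
    snp_action <- "kept"
    for (j in seq_len(t_n - 1)) {
      o <- others[[j]][idx[[j + 1]][i], ]
      res <- resolve_alleles(x$EA, x$OA, x$EAF, o$EA, o$OA, o$EAF,
                             palindromic_eaf_limit)
      if (startsWith(res$action, "dropped")) {
        keep[i] <- FALSE
        snp_action <- res$action
        break
      }
      if (res$flip) {
        beta[i, j + 1] <- -o$BETA
        eaf[i, j + 1] <- if (is.na(o$EAF)) NA_real_ else 1 - o$EAF
      } else {
        beta[i, j + 1] <- o$BETA
        eaf[i, j + 1] <- o$EAF
      }
      se[i, j + 1] <- o$SE; pp[i, j + 1] <- o$P; nn[i, j + 1] <- o$N
      if (res$action == "flipped" || res$flip) flip_any[i] <- TRUE
    }
    action[common[i]] <- if (keep[i] && flip_any[i]) "flipped"
                         else if (keep[i]) "kept" else snp_action
  }
  kept_idx <- which(keep)
  drop_log <- data.frame(SNP = names(action), action = unname(action),
                         stringsAsFactors = FALSE)
  h <- harmonized_set(
    snp_id = common[kept_idx], traits = labels,
    beta = beta[kept_idx, , drop = FALSE],
    se = se[kept_idx, , drop = FALSE],
    eaf = eaf[kept_idx, , drop = FALSE],
    p = pp[kept_idx, , drop = FALSE],
    n = nn[kept_idx, , drop = FALSE],
    chrom = exposure$CHR[idx[[1]]][kept_idx],
    pos = exposure$BP[idx[[1]]][kept_idx],
    drop_log = drop_log)
  attr(h, "EA") <- exposure$EA[idx[[1]]][kept_idx]
  attr(h, "OA") <- exposure$OA[idx[[1]]][kept_idx]
  h
}
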