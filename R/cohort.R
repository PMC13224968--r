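#' Construct a survival cohort
#'
#' A cohort bundles a numeric subjects-by-features matrix with right-censored
#' survival outcomes. It is the common currency of every model-fitting,
#' evaluation and attribution function in the package.
#'
#' @param features Numeric matrix (or data frame coercible to one), one row
#'   per subject, with unique column names.
#' @param time Non-negative observed time per subject (years on the analysis
#'   time scale, e.g. years since study entry at age 55).
#' @param event Event indicator per subject: 1 = onset observed,
#'   0 = right-censored.
#' @param subject_ids Optional subject labels; defaults to `S1..Sn`.
#' @return An object of class `cohort` with elements `features`, `time`,
#'   `event`, `subject_ids`, `feature_names`.
#' @export
cohort <- function(features, time, event, subject_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  if (anyDuplicated(colnames(features))) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (length(time) != n || length(event) != n) {
    stop("time/event length must equal the number of feature rows",
         call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("time must be non-negative and finite", call. = FALSE)
  }
  if (any(!event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (anyNA(features)) {
    stop("features must not contain missing values; apply a missingness ",
         "policy before constructing the cohort", call. = FALSE)
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  if (length(subject_ids) != n || anyDuplicated(subject_ids)) {
    stop("subject_ids must be unique and match the number of subjects",
         call. = FALSE)
  }
  rownames(features) <- subject_ids
  structure(
    list(features = features,
         time = as.numeric(time),
         event = as.integer(event),
         subject_ids = as.character(subject_ids),
         feature_names = colnames(features)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d features; %d events (%.1f%%)\n",
              nrow(x$features), ncol(x$features), sum(x$event),
              100 * mean(x$event)))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$features)

#' Subset a cohort by subjects and/or features
#'
#' @param x A [cohort].
#' @param i Subject index (integer, logical or character).
#' @param j Feature index (integer, logical or character).
#' @param ... Unused.
#' @export
`[.cohort` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$features))
  if (missing(j)) j <- seq_len(ncol(x$features))
  cohort(x$features[i, j, drop = FALSE], x$time[i], x$event[i],
         x$subject_ids[i])
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(subject_id = x$subject_ids, time = x$time, event = x$event,
             x$features, check.names = FALSE, row.names = NULL)
}

#' Encode an APOE genotype label as carrier indicators
#'
#' Converts unordered allele-pair labels such as `"E3/E4"` into three binary
#' carrier indicators (carries E2, carries E3, carries E4). Indicator `j` is
#' 1 when allele `j` appears at least once in the pair, so homozygotes and
#' heterozygotes of the same allele are not distinguished.
#'
#' @param genotype Character vector of labels, each two alleles from
#'   \{E2, E3, E4\} separated by `/` (order irrelevant).
#' @return Integer matrix with columns `APOE_E2`, `APOE_E3`, `APOE_E4`,
#'   one row per input label.
#' @examples
#' encode_apoe(c("E3/E4", "E2/E2"))
#' @export
encode_apoe <- function(genotype) {
  alleles <- c("E2", "E3", "E4")
  out <- matrix(0L, nrow = length(genotype), ncol = 3,
                dimnames = list(NULL, paste0("APOE_", alleles)))
  for (i in seq_along(genotype)) {
    toks <- toupper(trimws(strsplit(genotype[i], "/", fixed = TRUE)[[1]]))
    if (length(toks) != 2L) {
      stop(sprintf("APOE genotype '%s' is not an allele pair", genotype[i]),
           call. = FALSE)
    }
    bad <- setdiff(toks, alleles)
    if (length(bad)) {
      stop(sprintf("unknown APOE allele token '%s' in genotype '%s'",
                   bad[1], genotype[i]), call. = FALSE)
    }
    out[i, paste0("APOE_", unique(toks))] <- 1L
  }
  out
}

#' Encode diploid SNP calls as carrier indicators
#'
#' Converts per-subject alternate-allele dosages (0 = hom-ref, 1 = het,
#' 2 = hom-alt, `NA` = missing) into binary features. The default
#' `"carrier_pair"` encoding emits two indicators per variant — carries the
#' reference allele, carries the alternate allele — so a heterozygote is
#' (1, 1); `"alt_carrier"` emits a single carries-alternate indicator.
#'
#' @param dosage Integer matrix or vector of alt-allele dosages in
#'   \{0, 1, 2, NA\}; columns are variants, named.
#' @param encoding `"carrier_pair"` (default) or `"alt_carrier"`.
#' @param missing `"impute_ref"` (default: missing calls become hom-ref,
#'   with a warning) or `"error"`.
#' @return Integer matrix of indicators. Under `"carrier_pair"`, columns are
#'   `<variant>_ref` and `<variant>_alt` for each input column.
#' @examples
#' encode_snp_indicators(matrix(c(0, 1, 2), ncol = 1,
#'                              dimnames = list(NULL, "rs123")))
#' @export
encode_snp_indicators <- function(dosage,
                                  encoding = c("carrier_pair", "alt_carrier"),
                                  missing = c("impute_ref", "error")) {
  encoding <- match.arg(encoding)
  missing <- match.arg(missing)
  if (is.null(dim(dosage))) {
    dosage <- matrix(dosage, ncol = 1,
                     dimnames = list(NULL, "snp"))
  }
  dosage <- as.matrix(dosage)
  if (any(!dosage %in% c(0, 1, 2, NA))) {
    stop("dosage values must be 0, 1, 2 or NA (alleles outside {ref, alt} ",
         "are not representable)", call. = FALSE)
  }
  if (anyNA(dosage)) {
    if (missing == "error") {
      stop("missing genotype calls present and missing policy is 'error'",
           call. = FALSE)
    }
    warning(sprintf("%d missing genotype call(s) imputed to hom-ref",
                    sum(is.na(dosage))), call. = FALSE)
    dosage[is.na(dosage)] <- 0
  }
  vn <- colnames(dosage)
  if (is.null(vn)) vn <- paste0("snp", seq_len(ncol(dosage)))
  if (encoding == "alt_carrier") {
    out <- (dosage >= 1) + 0L
    dimnames(out) <- list(rownames(dosage), paste0(vn, "_alt"))
    return(out)
  }
  ref <- (dosage <= 1) + 0L
  alt <- (dosage >= 1) + 0L
  out <- matrix(0L, nrow = nrow(dosage), ncol = 2L * ncol(dosage),
                dimnames = list(rownames(dosage), NULL))
  out[, seq(1, ncol(out), by = 2)] <- ref
  out[, seq(2, ncol(out), by = 2)] <- alt
  colnames(out) <- as.vector(rbind(paste0(vn, "_ref"), paste0(vn, "_alt")))
  out
}

#' Read a subject-level feature table into a cohort
#'
#' Reads a delimited text file with a header row containing a time column,
#' an event column, optionally a subject-id column, and numeric feature
#' columns (all remaining columns by default).
#'
#' @param path File path (CSV by default; `sep` passes through).
#' @param time_col,event_col,id_col Column names for the survival outcome
#'   and optional subject ids.
#' @param feature_cols Optional character vector selecting/ordering feature
#'   columns; default: every column not otherwise assigned.
#' @param sep Field separator, default `","`.
#' @return A [cohort].
#' @export
read_feature_table <- function(path, time_col = "time", event_col = "event",
                               id_col = NULL, feature_cols = NULL,
                               sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(time_col, event_col, id_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("required column '%s' is missing from %s", col, path),
           call. = FALSE)
    }
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(df), c(time_col, event_col, id_col))
  } else if (!all(feature_cols %in% names(df))) {
    stop(sprintf("feature column(s) not found: %s",
                 paste(setdiff(feature_cols, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  feats <- df[feature_cols]
  non_num <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(non_num)) {
    stop(sprintf("non-numeric value(s) in feature column(s): %s",
                 paste(non_num, collapse = ", ")), call. = FALSE)
  }
  ids <- if (is.null(id_col)) NULL else as.character(df[[id_col]])
  cohort(as.matrix(feats), df[[time_col]], df[[event_col]], ids)
}

#' Write a cohort to the canonical CSV layout
#'
#' Columns: `subject_id`, `time`, `event`, then the features in cohort
#' order. [read_feature_table()] with `id_col = "subject_id"` round-trips
#' the values exactly.
#'
#' @param x A [cohort].
#' @param path Output file path.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)
  # full-precision decimal rendering so the CSV round-trips bitwise
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Event-stratified k-fold assignment
#'
#' Partitions subjects into `k` folds whose sizes differ by at most one,
#' stratifying on the event indicator so each fold's event count is within
#' one of its proportional share. Deterministic given `seed`.
#'
#' @param event Event indicator vector (0/1), or a [cohort].
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed controlling the shuffle.
#' @return A list of class `fold_assignment`: `fold` (integer in `0:(k-1)`
#'   per subject), `k`, `seed`.
#' @export
stratified_kfold <- function(event, k = 5, seed = 1) {
  if (inherits(event, "cohort")) event <- event$event
  n <- length(event)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k must not exceed the number of subjects", call. = FALSE)
  fold <- integer(n)
  with_seed(seed, {
    # Rotating fold order shared across strata so the "+1" remainders of
    # different strata land on different folds, keeping overall sizes
    # within one of each other.
    fold_order <- sample.int(k) - 1L
    ptr <- 0L
    for (g in unique(sort(event))) {
      idx <- which(event == g)
      idx <- idx[sample.int(length(idx))]
      labs <- fold_order[((ptr + seq_along(idx) - 1L) %% k) + 1L]
      fold[idx] <- labs
      ptr <- (ptr + length(idx)) %% k
    }
  })
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> k = %d, seed = %d, sizes: %s\n",
              x$k, x$seed, paste(tabulate(x$fold + 1L, x$k), collapse = "/")))
  invisible(x)
}
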