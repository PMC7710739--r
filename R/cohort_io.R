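# Closed vocabularies used across the package.
TIMEPOINTS <- c("T1", "T2", "T3")
SUBTYPES <- c("ER+/HER2-", "ER+/HER2+", "HER2+/ER-", "TN")
PCR_LEVELS <- c("pCR", "RD")

#' Validate an expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix with unique
#' rownames (gene ids) and unique colnames (sample ids). On the TPM scale all
#' values must be non-negative.
#'
#' @param x numeric matrix.
#' @param nonneg require all values >= 0 (TPM scale).
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x, nonneg = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids")
  if (nonneg && any(x < 0))
    stop("negative values in TPM-scale expression matrix")
  invisible(x)
}

#' Validate a clinical table
#'
#' Required columns: `patient_id`, `sample_id`, `subtype`, `time`, `purity`,
#' `pcr`. Time points form a closed vocabulary T1/T2/T3; (patient, time)
#' pairs must be unique; purity lies in [0, 1].
#'
#' @param clinical data.frame.
#' @return `clinical`, invisibly.
#' @export
validate_clinical <- function(clinical) {
  need <- c("patient_id", "sample_id", "subtype", "time", "purity", "pcr")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(clinical$time %in% TIMEPOINTS))
    stop("unknown time labels: ",
         paste(setdiff(unique(clinical$time), TIMEPOINTS), collapse = ", "))
  if (anyDuplicated(clinical[, c("patient_id", "time")]))
    stop("duplicate (patient, time) pairs")
  if (anyDuplicated(clinical$sample_id)) stop("duplicate sample ids")
  if (any(clinical$purity < 0 | clinical$purity > 1, na.rm = TRUE))
    stop("purity out of [0, 1]")
  if (!all(clinical$pcr %in% PCR_LEVELS))
    stop("pcr must be one of: ", paste(PCR_LEVELS, collapse = ", "))
  invisible(clinical)
}

#' Read / write an expression matrix as TSV
#'
#' Genes as rows; first column holds the gene id, remaining columns one
#' sample each. Writers emit UTF-8 with Unix newlines.
#'
#' @param path file path.
#' @return `read_expression` returns a validated numeric matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty expression file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_expression(m, nonneg = FALSE)
  m
}

#' @rdname read_expression
#' @param expr numeric matrix (genes x samples).
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr, nonneg = FALSE)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a clinical table as CSV
#' @param path file path.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(tab)
  tab
}

#' @rdname read_clinical
#' @param clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(clinical, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. The description
#' is discarded, gene order preserved, in-set duplicates dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    nms[[i]] <- f[[1]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[[1]], "' deduplicated")
      genes <- genes[!duplicated(genes)]
    }
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(sets))
    writeLines(paste(c(nm, "na", sets[[nm]]), collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Percentage with half-away-from-zero rounding
#'
#' Computes 100 * numerator / denominator rounded half away from zero to the
#' requested number of decimals, matching how cohort percentages are
#' conventionally printed (e.g. 55 of 146 -> 38).
#'
#' @param numerator,denominator counts, 0 <= numerator <= denominator.
#' @param decimals 0 or 1 decimal places.
#' @return numeric percentage.
#' @export
percent_of <- function(numerator, denominator, decimals = 0) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must lie in [0, denominator]")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Consort-style cohort summary
#'
#' Counts and percentages of patients by pathologic response, subtype (at the
#' earliest sample per patient), and time-point availability.
#'
#' @param clinical clinical table.
#' @return data.frame with columns `section`, `level`, `count`, `denominator`,
#'   `percent`.
#' @export
consort_summary <- function(clinical) {
  validate_clinical(clinical)
  if (!nrow(clinical)) stop("empty clinical table")
  ord <- clinical[order(match(clinical$time, TIMEPOINTS)), ]
  pat <- ord[!duplicated(ord$patient_id), ]
  n <- nrow(pat)
  row <- function(section, level, count, denom)
    data.frame(section = section, level = level, count = count,
               denominator = denom, percent = percent_of(count, denom),
               stringsAsFactors = FALSE)
  out <- list()
  for (lv in PCR_LEVELS)
    out[[length(out) + 1L]] <- row("pcr", lv, sum(pat$pcr == lv), n)
  for (lv in intersect(SUBTYPES, unique(pat$subtype)))
    out[[length(out) + 1L]] <- row("subtype", lv, sum(pat$subtype == lv), n)
  for (tp in TIMEPOINTS)
    out[[length(out) + 1L]] <-
      row("time_available", tp,
          length(unique(clinical$patient_id[clinical$time == tp])), n)
  do.call(rbind, out)
}

#' Paired samples between two time points
#'
#' Maps each patient with samples at both time points to the (sample at
#' `time_a`, sample at `time_b`) pair; patients lacking either are excluded.
#'
#' @param clinical clinical table.
#' @param time_a,time_b distinct time-point labels.
#' @return data.frame `patient_id`, `sample_a`, `sample_b`.
#' @export
build_pairs <- function(clinical, time_a, time_b) {
  validate_clinical(clinical)
  if (!all(c(time_a, time_b) %in% TIMEPOINTS)) stop("unknown time point")
  if (identical(time_a, time_b)) stop("time_a and time_b must differ")
  a <- clinical[clinical$time == time_a, c("patient_id", "sample_id")]
  b <- clinical[clinical$time == time_b, c("patient_id", "sample_id")]
  m <- merge(a, b, by = "patient_id", suffixes = c("_a", "_b"))
  data.frame(patient_id = m$patient_id, sample_a = m$sample_id_a,
             sample_b = m$sample_id_b, stringsAsFactors = FALSE)
}
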