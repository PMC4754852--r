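# Data containers and delimited-text readers/writers.
#
# All matrices are plain numeric matrices (rownames = features, colnames =
# samples) carrying a class tag and a "platform_id" attribute; tables are
# data.frames with a class tag. Everything round-trips through
# tab-separated text at 6 significant digits.

RACE_LEVELS <- c("nH_White", "nH_Black", "Hispanic", "Asian", "Unknown")
STATUS_LEVELS <- c("positive", "negative", "unknown")

#' Construct a beta-value matrix
#'
#' A beta value is the methylation fraction at a CpG probe: 0 means fully
#' unmethylated, 1 fully methylated. Rows are probes, columns samples.
#'
#' @param values numeric matrix in \[0,1\] (NA allowed), rows = probes,
#'   columns = samples; must carry row and column names.
#' @param platform_id label for the array design.
#' @return a `beta_matrix` (numeric matrix with class and platform
#'   attributes).
#' @export
beta_matrix <- function(values, platform_id = "platform") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (%g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]))
  structure(values, platform_id = platform_id,
            class = c("beta_matrix", class(values)))
}

#' Construct a probe-to-gene annotation
#'
#' @param probe_id character vector of unique probe ids.
#' @param gene_symbol character vector of gene symbols (one per probe; many
#'   probes may share a gene). Symbols are whitespace-trimmed and matched
#'   case-sensitively throughout the package.
#' @param platform_id label for the array design.
#' @return a `probe_annotation` data.frame.
#' @export
probe_annotation <- function(probe_id, gene_symbol,
                             platform_id = "platform") {
  probe_id <- trimws(as.character(probe_id))
  gene_symbol <- trimws(as.character(gene_symbol))
  if (length(probe_id) != length(gene_symbol))
    stop("probe_id and gene_symbol lengths differ")
  if (anyDuplicated(probe_id))
    stop("duplicate probe id in annotation: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (any(!nzchar(gene_symbol)))
    stop("empty gene symbol for probe: ",
         paste(probe_id[!nzchar(gene_symbol)], collapse = ", "))
  structure(data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       stringsAsFactors = FALSE),
            platform_id = platform_id,
            class = c("probe_annotation", "data.frame"))
}

#' Construct a sample phenotype table
#'
#' Derives the combined hormone-receptor group: a tumor is ER/PR-positive
#' if either the estrogen or the progesterone receptor is positive,
#' ER/PR-negative only if both are negative; unknown in either receptor
#' (unless the other is positive) propagates to an unknown group.
#'
#' @param sample_id unique sample labels.
#' @param er_status,pr_status "positive", "negative" or "unknown".
#' @param age_years non-negative numeric age at diagnosis.
#' @param race_ethnicity one of nH_White, nH_Black, Hispanic, Asian,
#'   Unknown.
#' @return a `sample_table` data.frame with a derived `erpr_group` column.
#' @export
sample_table <- function(sample_id, er_status, pr_status, age_years,
                         race_ethnicity) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  er_status <- match_token(er_status, STATUS_LEVELS, "ER status")
  pr_status <- match_token(pr_status, STATUS_LEVELS, "PR status")
  race_ethnicity <- match_token(race_ethnicity, RACE_LEVELS,
                                "race/ethnicity")
  age_years <- as.numeric(age_years)
  if (anyNA(age_years) || any(age_years < 0))
    stop("age_years must be non-negative numbers")
  grp <- ifelse(er_status == "positive" | pr_status == "positive",
                "positive",
         ifelse(er_status == "negative" & pr_status == "negative",
                "negative", "unknown"))
  structure(data.frame(sample_id = sample_id, er_status = er_status,
                       pr_status = pr_status, erpr_group = grp,
                       age_years = age_years,
                       race_ethnicity = race_ethnicity,
                       stringsAsFactors = FALSE),
            class = c("sample_table", "data.frame"))
}

match_token <- function(x, levels, what) {
  x <- trimws(as.character(x))
  bad <- !(x %in% levels)
  if (any(bad))
    stop(sprintf("unrecognized %s token(s): %s (expected one of %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")))
  x
}

#' Read a beta-value matrix from tab-separated text
#'
#' Expects a header row of sample ids, a first column of probe ids, and
#' numeric cells (or the missing token). Values outside \[0,1\] and
#' non-numeric cells are reported with their probe and sample.
#'
#' @param path file path.
#' @param missing_token string standing for a missing value (default "NA").
#' @param platform_id label attached to the returned matrix.
#' @return a [beta_matrix].
#' @export
read_beta_matrix <- function(path, missing_token = "NA",
                             platform_id = "platform") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2) stop("malformed header in '", path,
                         "': need probe id column plus >= 1 sample")
  probes <- trimws(dt[[1]])
  samples <- trimws(colnames(dt)[-1])
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header of '", path, "': ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(probes))
    stop("duplicate probe ids in '", path, "': ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  cells <- as.matrix(dt[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  vals[cells == missing_token] <- NA_real_
  bad <- which(is.na(vals) & cells != missing_token, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at probe '%s', sample '%s' in '%s'",
                 cells[bad[1, , drop = FALSE]], probes[bad[1, 1]],
                 samples[bad[1, 2]], path))
  dimnames(vals) <- list(probes, samples)
  beta_matrix(vals, platform_id = platform_id)
}

#' Write a beta-value (or gene-methylation) matrix as tab-separated text
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param missing_token token written for NA cells.
#' @param id_column header name of the feature-id column.
#' @return `invisible(path)`.
#' @export
write_beta_matrix <- function(x, path, missing_token = "NA",
                              id_column = "probe_id") {
  body <- matrix(fmt_num(x, na = missing_token), nrow = nrow(x))
  out <- cbind(rownames(x), body)
  colnames(out) <- c(id_column, colnames(x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation manifest
#'
#' Consumes only the probe-id and gene-symbol columns of a manifest;
#' additional columns (synonyms, accessions, ...) are ignored.
#'
#' @param path file path to a delimited manifest.
#' @param probe_col,gene_col column names to consume.
#' @param platform_id label attached to the annotation.
#' @return a [probe_annotation].
#' @export
read_probe_annotation <- function(path, probe_col = "probe_id",
                                  gene_col = "gene_symbol",
                                  platform_id = "platform") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(probe_col, gene_col), colnames(dt))
  if (length(missing_cols) > 0)
    stop("annotation file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  probe_annotation(dt[[probe_col]], dt[[gene_col]],
                   platform_id = platform_id)
}

#' Read a sample phenotype table
#'
#' @param path delimited file with columns sample_id, er_status, pr_status,
#'   age_years, race_ethnicity.
#' @return a [sample_table] with the derived ER/PR group.
#' @export
read_sample_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "er_status", "pr_status", "age_years",
            "race_ethnicity")
  missing_cols <- setdiff(need, colnames(dt))
  if (length(missing_cols) > 0)
    stop("sample table '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  age <- suppressWarnings(as.numeric(dt$age_years))
  if (anyNA(age))
    stop("unparseable age for sample(s): ",
         paste(dt$sample_id[is.na(age)], collapse = ", "))
  sample_table(dt$sample_id, dt$er_status, dt$pr_status, age,
               dt$race_ethnicity)
}

#' Write a result collection as tab-separated text
#'
#' Any data.frame-coercible result (association tables, direction
#' summaries, SAM feature tables, ...) is written with a header; numeric
#' columns at 6 significant digits, so write-then-read is the identity at
#' that precision.
#'
#' @param x a data.frame or an object with an `as.data.frame` method.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
    if (is.logical(df[[j]])) df[[j]] <- ifelse(df[[j]], "TRUE", "FALSE")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Categorical age bands used in cohort description tables
#'
#' @param age_years numeric ages.
#' @return factor with levels `<50`, `50-59`, `60-79`, `80+`.
#' @export
age_bands <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 50, 60, 80, Inf), right = FALSE,
      labels = c("<50", "50-59", "60-79", "80+"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix [%s]: %d probes x %d samples, %d missing\n",
              attr(x, "platform_id"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf("probe_annotation [%s]: %d probes, %d genes\n",
              attr(x, "platform_id"), nrow(x),
              length(unique(x$gene_symbol))))
  invisible(x)
}
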