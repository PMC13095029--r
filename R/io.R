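# Delimited-table dialects shared by all pipeline stages: tab-separated,
# UTF-8, '.' decimal, missing = empty field, preceded by '# key: value'
# metadata lines (stage, seed, config hash) so every output records how it
# was produced.

.schemas <- list(
  phenotype = c("pair_id", "mother_id", "cohort_id", "birth_weight", "sex",
                "gestational_age", "batch",
                paste0("mother_pc", 1:5), paste0("child_pc", 1:5),
                "year_of_birth"),
  hla = c("sample_id", "allele1", "allele2", "c2_dosage", "quality"),
  kir = c("sample_id", "locus", "state", "posterior"),
  results = c("cohort", "model_id", "term", "estimate", "se", "ci_low",
              "ci_high", "p", "n_used")
)

.write_delim <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  }
  out <- df
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])
      v[is.na(out[[cn]])] <- NA_character_
      out[[cn]] <- v
    }
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

.read_delim <- function(path, schema, numeric_cols) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines)
  meta <- list()
  if (length(meta_lines)) {
    kv <- sub("^#\\s*", "", lines[meta_lines])
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- stats::setNames(as.list(vals), keys)
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), meta_lines)],
                          header = TRUE, sep = "\t", quote = "",
                          na.strings = "", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols)) {
    stop("table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         "; expected schema: ", paste(schema, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), schema)
  if (length(unknown) && !all(unknown %in% c("reported_weights"))) {
    stop("table ", path, " has unknown column(s): ",
         paste(setdiff(unknown, "reported_weights"), collapse = ", "),
         "; expected schema: ", paste(schema, collapse = ", "),
         call. = FALSE)
  }
  for (cn in intersect(numeric_cols, names(df))) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  attr(df, "meta") <- meta
  df
}

#' Read and write the pipeline's delimited tables
#'
#' Four table dialects tie the stages together: the phenotype/covariate
#' table (one row per mother-offspring pair), the HLA call table, the
#' KIR*IMP-style long posterior table, and the per-cohort model result
#' table. All are tab-separated UTF-8 text with empty fields for missing
#' values, preceded by `# key: value` metadata lines; writing then reading a
#' table is the identity on values and column order. Readers validate the
#' schema (naming any missing column), reject duplicated `pair_id`s in the
#' phenotype table, and check that each KIR sample/locus posterior block
#' sums to 1 within `tol`.
#'
#' @param df Table to write.
#' @param path File path.
#' @param meta Named list written as `# key: value` header lines.
#' @param tol Posterior sum tolerance for the KIR table.
#' @return Readers return the table with a `"meta"` attribute; writers
#'   return `path` invisibly.
#' @name pipeline_tables
NULL

#' @rdname pipeline_tables
#' @export
write_phenotype_table <- function(df, path, meta = list()) {
  .write_delim(df, path, meta)
}

#' @rdname pipeline_tables
#' @export
read_phenotype_table <- function(path) {
  df <- .read_delim(path, .schemas$phenotype,
                    c("birth_weight", "gestational_age",
                      paste0("mother_pc", 1:5), paste0("child_pc", 1:5),
                      "year_of_birth"))
  if (anyDuplicated(df$pair_id)) {
    stop("duplicated pair_id in ", path, ": ",
         paste(unique(df$pair_id[duplicated(df$pair_id)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname pipeline_tables
#' @export
write_hla_table <- function(df, path, meta = list()) {
  .write_delim(df, path, meta)
}

#' @rdname pipeline_tables
#' @export
read_hla_table <- function(path) {
  .read_delim(path, .schemas$hla, c("c2_dosage", "quality"))
}

#' @rdname pipeline_tables
#' @export
write_kir_table <- function(df, path, meta = list()) {
  .write_delim(df, path, meta)
}

#' @rdname pipeline_tables
#' @export
read_kir_table <- function(path, tol = 1e-6) {
  df <- .read_delim(path, .schemas$kir, c("state", "posterior"))
  key <- paste(df$sample_id, df$locus)
  sums <- tapply(df$posterior, key, sum)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    stop("KIR posteriors in ", path, " do not sum to 1 (tolerance ", tol,
         ") for: ", paste(utils::head(names(sums)[off], 5L), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname pipeline_tables
#' @export
write_results_table <- function(df, path, meta = list()) {
  .write_delim(df, path, meta)
}

#' @rdname pipeline_tables
#' @export
read_results_table <- function(path) {
  df <- .read_delim(path, .schemas$results,
                    c("model_id", "estimate", "se", "ci_low", "ci_high",
                      "p", "n_used"))
  df$model_id <- as.integer(df$model_id)
  df$n_used <- as.integer(df$n_used)
  df
}

#' Read and write Oxford HAPS/SAMPLE haplotype files
#'
#' A HAPS file holds one variant per row: five leading fields (chromosome,
#' snp id, position, allele a, allele b) followed by `2N` phased 0/1
#' haplotype columns; the companion SAMPLE file uses the Oxford two-header
#' convention (a column-name row then a type row) with one row per
#' individual. Allele-b frequencies computed from the haplotype columns
#' equal the direct allele count divided by `2N` exactly.
#'
#' @param path File path.
#' @param haps A haplotype panel: list with `snps` (data frame: `chrom`,
#'   `snp_id`, `position`, `allele_a`, `allele_b`), `haplotypes` (integer
#'   0/1 matrix, one row per variant) and optionally `samples`.
#' @param samples Sample table from [read_sample_file()], used to check the
#'   haplotype column count.
#' @return `read_haps()` returns the panel list; `haps_allele_freq()` the
#'   per-variant allele-b frequency vector.
#' @name haps_io
NULL

#' @rdname haps_io
#' @export
read_haps <- function(path, samples = NULL) {
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 7L) stop("HAPS file has no haplotype columns",
                           call. = FALSE)
  n_hap <- ncol(raw) - 5L
  if (n_hap %% 2L != 0L) {
    stop("odd haplotype column count (", n_hap, ") in ", path, call. = FALSE)
  }
  hap <- as.matrix(raw[, -(1:5), drop = FALSE])
  storage.mode(hap) <- "integer"
  if (any(!hap %in% c(0L, 1L))) {
    stop("haplotype columns must be 0/1", call. = FALSE)
  }
  dimnames(hap) <- NULL
  snps <- data.frame(
    chrom = raw[[1]], snp_id = raw[[2]],
    position = as.numeric(raw[[3]]),
    allele_a = raw[[4]], allele_b = raw[[5]],
    stringsAsFactors = FALSE
  )
  if (!is.null(samples) && nrow(samples) * 2L != n_hap) {
    stop("SAMPLE file lists ", nrow(samples), " individuals but HAPS has ",
         n_hap, " haplotype columns", call. = FALSE)
  }
  list(snps = snps, haplotypes = hap, samples = samples)
}

#' @rdname haps_io
#' @export
write_haps <- function(haps, path) {
  snps <- haps$snps
  body <- cbind(snps$chrom, snps$snp_id,
                format(snps$position, scientific = FALSE, trim = TRUE),
                snps$allele_a, snps$allele_b, haps$haplotypes)
  utils::write.table(body, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname haps_io
#' @export
read_sample_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("SAMPLE file needs the two Oxford header rows",
                               call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  df <- utils::read.table(text = lines[-(1:2)], header = FALSE, sep = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) != length(header)) {
    stop("SAMPLE body and header disagree on column count", call. = FALSE)
  }
  names(df) <- header
  attr(df, "type_row") <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  df
}

#' @rdname haps_io
#' @export
write_sample_file <- function(samples, path) {
  type_row <- attr(samples, "type_row")
  if (is.null(type_row)) {
    type_row <- c("0", "0", "0", rep("D", max(0L, ncol(samples) - 3L)))
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(names(samples), collapse = " "), con)
  writeLines(paste(type_row, collapse = " "), con)
  utils::write.table(samples, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname haps_io
#' @export
haps_allele_freq <- function(haps) {
  stats::setNames(rowMeans(haps$haplotypes), haps$snps$snp_id)
}
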