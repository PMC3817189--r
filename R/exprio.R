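# ---- expression matrices ----------------------------------------------------

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of variance-stabilised
#' (generalized-log scale) values with genes in rows and samples in columns.
#' Row and column names are the gene and sample identifiers; both must be
#' unique and every value finite.  The method's correlations assume complete
#' data, so missing values are rejected here rather than silently imputed
#' downstream; [drop_incomplete_genes()] is the explicit pre-step.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @return the validated matrix, invisibly classed as it came in.
#' @export
validate_expression <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression data must be a numeric matrix (genes x samples)")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix must carry gene row names and sample column names")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gid[bad[1]], sid[bad[2]]))
  }
  invisible(values)
}

#' Read a tab-delimited expression table
#'
#' Expects genes in rows and samples in columns: the first row holds sample
#' identifiers, the first column gene identifiers.  File order is preserved.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene id column plus >=1 sample")
  gid <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     v[bad[1]], gid[bad[1]], colnames(vals)[j]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gid
  validate_expression(m)
  m
}

#' Write an expression matrix as a tab-delimited table
#'
#' Inverse of [read_expression_table()]; values are written at full precision
#' so that a write/read round trip reproduces them exactly.
#'
#' @param X expression matrix.
#' @param path output path.
#' @export
write_expression_table <- function(X, path) {
  validate_expression(X)
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes with missing values
#'
#' Optional pre-step for matrices that still contain `NA`s: removes every gene
#' row with any missing entry and logs how many were dropped.
#'
#' @param values numeric matrix with dimnames (may contain `NA`).
#' @return the complete-row submatrix.
#' @export
drop_incomplete_genes <- function(values) {
  keep <- stats::complete.cases(values)
  if (any(!keep))
    cgsa_log("dropped %d/%d genes with missing values", sum(!keep), nrow(values))
  values[keep, , drop = FALSE]
}

#' Collapse duplicate gene identifiers to the highest-variance row
#'
#' Keeps, for each repeated identifier, the row with the largest variance
#' across samples (the usual probe-to-gene reduction); off by default in all
#' pipelines, exposed for users whose platform annotation maps several rows to
#' one gene.
#'
#' @param values numeric matrix whose row names may repeat.
#' @return matrix with unique row names.
#' @export
collapse_duplicate_genes <- function(values) {
  v <- apply(values, 1, stats::var)
  ord <- order(rownames(values), -v)
  keep <- ord[!duplicated(rownames(values)[ord])]
  out <- values[sort(keep), , drop = FALSE]
  if (nrow(out) < nrow(values))
    cgsa_log("collapsed %d duplicate rows to %d unique genes",
             nrow(values) - nrow(out), nrow(out))
  out
}

# ---- GMT gene set files -----------------------------------------------------

#' Read a GMT gene set file
#'
#' Standard tab-separated GMT dialect: one set per line with set id,
#' description, then member gene identifiers.  Member order is preserved.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of members; each element carries a
#'   `description` attribute.  Empty file gives an empty list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list(); ids <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need id, description, members",
                   i, length(f)))
    members <- f[-(1:2)]
    attr(members, "description") <- f[2]
    out[[length(out) + 1L]] <- members
    ids <- c(ids, f[1])
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate set id(s) in GMT: ", paste(dup, collapse = ", "))
  names(out) <- ids
  out
}

#' Write a GMT gene set file
#'
#' @param sets named list of member character vectors; a `description`
#'   attribute per element is used as the GMT description field ("" otherwise).
#'   A `cgs_collection` may be passed directly: its sets are written with the
#'   center gene first and the score in the description.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "cgs_collection")) sets <- as_gmt(sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a non-empty id")
  lines <- vapply(seq_along(sets), function(i) {
    m <- sets[[i]]
    if (!length(m)) stop("set '", names(sets)[i], "' has an empty member list")
    d <- attr(m, "description"); if (is.null(d)) d <- ""
    paste(c(names(sets)[i], d, as.character(m)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- phenotype tables -------------------------------------------------------

#' Read a phenotype table
#'
#' TSV with a header and one row per sample; the first column (or the column
#' named by `id_col`) holds sample identifiers.  `schema` declares the type of
#' each variable: `"categorical"` columns become factors over their observed
#' non-missing levels, `"quantitative"` columns are parsed as reals.  Empty
#' cells and `"NA"` are recorded as missing.
#'
#' @param path path to a TSV file.
#' @param schema named character vector mapping column names to
#'   `"categorical"` or `"quantitative"`; undeclared columns are left as read.
#' @param id_col name of the sample id column (default: first column).
#' @return data.frame with `sample_id` first; attribute `schema` records the
#'   declarations used.
#' @export
read_phenotype_table <- function(path, schema = NULL, id_col = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (is.null(id_col)) id_col <- names(df)[1]
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in phenotype table")
  df[[id_col]] <- NULL
  out <- data.frame(sample_id = ids, df, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (nm in names(schema)) {
    if (!nm %in% names(out)) stop("schema names unknown column '", nm, "'")
    if (schema[[nm]] == "categorical") {
      f <- factor(out[[nm]])
      if (nlevels(f) < 2L)
        stop("categorical column '", nm, "' has fewer than 2 observed levels")
      out[[nm]] <- f
    } else if (schema[[nm]] == "quantitative") {
      suppressWarnings(v <- as.numeric(out[[nm]]))
      bad <- which(is.na(v) & !is.na(out[[nm]]))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in quantitative column '%s'",
                     out[[nm]][bad[1]], nm))
      out[[nm]] <- v
    } else stop("unknown schema type '", schema[[nm]], "'")
  }
  attr(out, "schema") <- schema
  out
}

#' Align a phenotype table with an expression matrix
#'
#' Keeps exactly the samples present in both, in the column order of the
#' expression matrix; samples on either side without a partner are reported
#' as warnings, never as failures.
#'
#' @param X expression matrix.
#' @param pheno data.frame from [read_phenotype_table()].
#' @return list with the column-subset matrix `X` and row-subset `pheno`.
#' @export
join_phenotypes <- function(X, pheno) {
  sid <- colnames(X)
  common <- intersect(sid, pheno$sample_id)
  lostX <- setdiff(sid, common)
  lostP <- setdiff(pheno$sample_id, common)
  if (length(lostX))
    warning(length(lostX), " expression sample(s) without phenotype row: ",
            paste(utils::head(lostX, 5), collapse = ", "))
  if (length(lostP))
    warning(length(lostP), " phenotype row(s) without expression sample: ",
            paste(utils::head(lostP, 5), collapse = ", "))
  keep <- sid[sid %in% common]
  list(X = X[, keep, drop = FALSE],
       pheno = pheno[match(keep, pheno$sample_id), , drop = FALSE])
}

#' Read a plain gene list (one identifier per line)
#'
#' Used for gene class memberships (e.g. highly/lowly expressed gene lists)
#' and mapping targets.
#'
#' @param path path to a text file.
#' @return character vector of identifiers, blanks removed.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

# ---- config & logging -------------------------------------------------------

#' Read a YAML run configuration
#'
#' One block per pipeline stage (e.g. `extract:`, `cluster:`); every CLI flag
#' has a config twin and the CLI value wins when both are given.
#'
#' @param path YAML file path.
#' @return named list of stage blocks (empty list for an empty file).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

#' Log a message with a timestamp
#'
#' All pipeline stages log their parameter set and input digests through this
#' single hook so runs are reproducible from the transcript.
#'
#' @param fmt `sprintf` format string.
#' @param ... values for `fmt`.
#' @export
cgsa_log <- function(fmt, ...) {
  message(sprintf("[cgsa %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' MD5 digest of an input file
#'
#' @param path file path.
#' @return hex digest string, for run logs.
#' @export
input_digest <- function(path) unname(tools::md5sum(path))
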