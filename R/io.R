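#' Read a features-by-samples expression matrix
#'
#' Reads a delimited text file whose first column holds feature identifiers
#' (e.g. gene symbols) and whose header row holds sample identifiers. The
#' delimiter is auto-detected among tab and comma; files that parse to a
#' single column under both candidates are rejected rather than guessed.
#'
#' @param path Path to a delimited text file.
#' @param omics_type `"counts"` for raw RNA-seq counts (validated as
#'   non-negative integers) or `"log_intensity"` for already-log2 data.
#' @return A numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression_matrix <- function(path, omics_type = c("counts", "log_intensity")) {
  omics_type <- match.arg(omics_type)
  df <- read_delimited(path)
  if (ncol(df) < 2L) {
    stop("expression file must have a feature-id column plus at least one sample column: ", path)
  }
  feats <- as.character(df[[1L]])
  dup <- unique(feats[duplicated(feats)])
  if (length(dup)) {
    stop("duplicate feature ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  samp <- colnames(df)[-1L]
  if (anyDuplicated(samp)) {
    stop("duplicate sample ids in header of ", path)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    loc <- if (nrow(bad)) {
      paste0(" first at feature '", feats[bad[1L, 1L]], "', sample '", samp[bad[1L, 2L]], "'")
    } else ""
    stop("non-numeric value in expression matrix ", path, ";", loc)
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop("non-numeric value in expression matrix ", path,
         "; first at feature '", feats[bad[1L, 1L]], "', sample '", samp[bad[1L, 2L]], "'")
  }
  rownames(mat) <- feats
  if (omics_type == "counts") {
    if (any(mat < 0)) {
      bad <- which(mat < 0, arr.ind = TRUE)
      stop("negative count at feature '", feats[bad[1L, 1L]], "', sample '", samp[bad[1L, 2L]], "'")
    }
    if (any(mat != round(mat))) {
      bad <- which(mat != round(mat), arr.ind = TRUE)
      stop("non-integer count '", mat[bad[1L, , drop = FALSE]], "' at feature '",
           feats[bad[1L, 1L]], "', sample '", samp[bad[1L, 2L]], "'")
    }
  }
  mat
}

#' Read sample-to-dose metadata
#'
#' Expects a delimited file with a sample-id column and a dose column (named
#' `sample`/`sample_id` and `dose`/`concentration`, case-insensitively; if no
#' named match is found the first two columns are used). Extra covariate
#' columns are preserved in the `"covariates"` attribute but are not used in
#' modeling.
#'
#' @param path Path to a delimited text file.
#' @return A named numeric vector of doses, names are sample ids.
#' @export
read_metadata <- function(path) {
  df <- read_delimited(path)
  if (ncol(df) < 2L) stop("metadata file needs at least sample and dose columns: ", path)
  nm <- tolower(colnames(df))
  si <- which(nm %in% c("sample", "sample_id", "sampleid"))[1L]
  di <- which(nm %in% c("dose", "concentration"))[1L]
  if (is.na(si)) si <- 1L
  if (is.na(di)) di <- setdiff(seq_len(ncol(df)), si)[1L]
  ids <- as.character(df[[si]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  doses <- suppressWarnings(as.numeric(df[[di]]))
  if (anyNA(doses)) stop("non-numeric dose for sample(s): ",
                         paste(ids[is.na(doses)], collapse = ", "))
  if (any(doses < 0)) stop("negative dose for sample(s): ",
                           paste(ids[doses < 0], collapse = ", "))
  out <- setNames(doses, ids)
  extra <- df[, -c(si, di), drop = FALSE]
  if (ncol(extra)) attr(out, "covariates") <- extra
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GSEA dialect: one set per line, tab-separated fields
#' `name`, `description`, then one field per member. Duplicate members
#' within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of `gene_set` objects with
#'   fields `name`, `description` and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " ('", f[1L], "') has no members")
    sets[[i]] <- gene_set(name = f[1L], description = f[2L], members = members)
  }
  nms <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate gene set names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  structure(setNames(sets, nms), class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set_collection` or list of `gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description %||% "")) s$description else "na", s$members),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param name Set name (unique within a collection).
#' @param members Character vector of feature ids; deduplicated.
#' @param description Free-text description (GMT second field).
#' @param id Optional external identifier (e.g. an MSigDB accession).
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members, description = "", id = NULL) {
  members <- unique(as.character(members))
  if (!length(members)) stop("gene set '", name, "' has no members")
  structure(list(name = as.character(name), id = id,
                 description = as.character(description), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, " (", length(x$members), " members)\n", sep = "")
  invisible(x)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x), " sets\n", sep = "")
  for (s in head(x, 10L)) cat("  ", s$name, ": ", length(s$members), " members\n", sep = "")
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Align an expression matrix with dose metadata
#'
#' Restricts both inputs to their common sample ids, orders samples by dose
#' then id (so downstream results do not depend on file order), and records
#' dropped ids. A warning state is recorded when there are fewer distinct
#' dose levels than models need (4 for splines, 3 for linear trends).
#'
#' @param expression Numeric matrix, features x samples.
#' @param doses Named numeric dose vector (from [read_metadata()]).
#' @param omics_type `"counts"` or `"log_intensity"`.
#' @param feature_id_kind Free-text label for the feature identifier type.
#' @return A `dose_response_dataset` with elements `expression`, `doses`,
#'   `omics_type`, `feature_id_kind`, `dropped_samples` and `warnings`.
#' @export
align_dataset <- function(expression, doses,
                          omics_type = c("counts", "log_intensity"),
                          feature_id_kind = "gene_symbol") {
  omics_type <- match.arg(omics_type)
  common <- intersect(colnames(expression), names(doses))
  if (!length(common)) stop("no common sample ids between expression matrix and metadata")
  dropped <- list(expression = setdiff(colnames(expression), common),
                  metadata   = setdiff(names(doses), common))
  d <- doses[common]
  ord <- order(d, names(d))
  d <- d[ord]
  mat <- expression[, names(d), drop = FALSE]
  n_levels <- length(unique(unname(d)))
  if (n_levels < 2L) stop("need at least 2 distinct dose levels, got ", n_levels)
  warn <- character()
  if (n_levels < 3L) {
    warn <- c(warn, sprintf("only %d distinct dose levels: linear trends need 3", n_levels))
  } else if (n_levels < 4L) {
    warn <- c(warn, sprintf("only %d distinct dose levels: cubic splines need 4, only linear trends will be fitted", n_levels))
  }
  structure(list(expression = mat, doses = d, omics_type = omics_type,
                 feature_id_kind = feature_id_kind,
                 dropped_samples = dropped, warnings = warn),
            class = "dose_response_dataset")
}

#' @export
print.dose_response_dataset <- function(x, ...) {
  cat("<dose_response_dataset> ", nrow(x$expression), " features x ",
      ncol(x$expression), " samples (", x$omics_type, ")\n", sep = "")
  cat("  dose levels: ", paste(signif(unique(unname(x$doses)), 4), collapse = ", "), "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Delimiter auto-detection: tab then comma; a file where neither splits the
# header into >1 field is ambiguous and rejected.
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  sep <- if (n_tab > 0L) "\t" else if (n_com > 0L) "," else
    stop("cannot detect delimiter (neither tab nor comma) in ", path)
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

#' Write an expression matrix to a delimited file
#'
#' @param mat Numeric matrix, features x samples.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @param id_column Header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, sep = "\t", id_column = "feature_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write sample-to-dose metadata to a delimited file
#'
#' @param doses Named numeric dose vector.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(doses, path, sep = "\t") {
  df <- data.frame(sample = names(doses), dose = unname(doses), stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
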