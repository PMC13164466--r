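#' @title Compound tables and split files
#' @name data_io
NULL

.check_dataset <- function(ds) {
  stopifnot(is.data.frame(ds),
            all(c("id", "smiles", "endpoint") %in% names(ds)))
  if (anyDuplicated(ds$id)) {
    dup <- ds$id[duplicated(ds$id)][1L]
    stop("duplicate compound id '", dup, "'")
  }
  if (any(!nzchar(trimws(ds$smiles)))) {
    stop("empty SMILES at row ", which(!nzchar(trimws(ds$smiles)))[1L])
  }
  invisible(ds)
}

#' Construct a compound dataset
#'
#' @param id Character vector of unique compound identifiers.
#' @param smiles Character vector of SMILES strings.
#' @param endpoint Numeric endpoint, e.g. log relative sweetness log(S).
#' @return A data.frame with columns `id`, `smiles`, `endpoint`.
#' @export
new_dataset <- function(id, smiles, endpoint) {
  ds <- data.frame(id = as.character(id), smiles = as.character(smiles),
                   endpoint = as.numeric(endpoint),
                   stringsAsFactors = FALSE)
  .check_dataset(ds)
}

#' Read a compound table
#'
#' Reads CSV/TSV (with a header) or SMI files into a dataset. SMI lines carry
#' whitespace-separated fields `SMILES [id [endpoint]]`; missing ids are
#' autogenerated, missing endpoints become `NA` (prediction-only input).
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"smi"` (default guessed from the
#'   extension).
#' @param id_col,smiles_col,endpoint_col Column names for csv/tsv input.
#' @return A dataset data.frame (`id`, `smiles`, `endpoint`), row order
#'   preserved.
#' @export
read_dataset <- function(path, format = NULL,
                         id_col = "id", smiles_col = "smiles",
                         endpoint_col = "endpoint") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", smi = "smi",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  format <- match.arg(format, c("csv", "tsv", "smi"))
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    ds <- do.call(rbind, lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 1L || length(f) > 3L) {
        stop("SMI row ", i, ": expected 1-3 whitespace fields, got ",
             length(f))
      }
      ep <- NA_real_
      if (length(f) == 3L) {
        ep <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(ep)) stop("SMI row ", i, ": non-numeric endpoint '",
                            f[3L], "'")
      }
      data.frame(id = if (length(f) >= 2L) f[2L] else paste0("cmpd", i),
                 smiles = f[1L], endpoint = ep, stringsAsFactors = FALSE)
    }))
    return(.check_dataset(ds))
  }
  tab <- utils::read.table(path, header = TRUE, sep = if (format == "csv") ","
                           else "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  for (col in c(id_col, smiles_col, endpoint_col)) {
    if (!col %in% names(tab)) {
      stop("missing column '", col, "' in ", path)
    }
  }
  ep <- suppressWarnings(as.numeric(tab[[endpoint_col]]))
  bad <- which(is.na(ep) & !is.na(tab[[endpoint_col]]))
  if (length(bad)) {
    stop("non-numeric endpoint '", tab[[endpoint_col]][bad[1L]],
         "' at row ", bad[1L])
  }
  .check_dataset(data.frame(id = tab[[id_col]], smiles = tab[[smiles_col]],
                            endpoint = ep, stringsAsFactors = FALSE))
}

#' Write a dataset as CSV
#'
#' @param ds Dataset data.frame.
#' @param path Output path.
#' @export
write_dataset <- function(ds, path) {
  .check_dataset(ds)
  utils::write.csv(ds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove duplicate structures
#'
#' Two compounds are duplicates when their SMILES strings are identical after
#' stripping all whitespace. The first occurrence is kept; later occurrences
#' are dropped and reported.
#'
#' @param ds Dataset data.frame.
#' @return List with `dataset` (retained rows, order preserved) and `removed`
#'   (data.frame `removed_id`, `duplicate_of`).
#' @export
deduplicate <- function(ds) {
  .check_dataset(ds)
  key <- gsub("[[:space:]]+", "", ds$smiles)
  dup <- duplicated(key)
  first_of <- ds$id[match(key, key)]
  removed <- data.frame(removed_id = ds$id[dup],
                        duplicate_of = first_of[dup],
                        stringsAsFactors = FALSE)
  list(dataset = ds[!dup, , drop = FALSE], removed = removed)
}

.roles <- c("A", "P", "C", "V")

.check_split <- function(split) {
  stopifnot(is.data.frame(split), all(c("id", "role") %in% names(split)))
  bad <- setdiff(unique(split$role), .roles)
  if (length(bad)) stop("unknown role letter '", bad[1L], "'")
  if (anyDuplicated(split$id)) {
    stop("duplicate id '", split$id[duplicated(split$id)][1L], "' in split")
  }
  invisible(split)
}

#' Read / write split assignments
#'
#' A split file is a two-column CSV `id,role` with roles in
#' A (active training), P (passive training), C (calibration),
#' V (validation).
#'
#' @param split Split data.frame (`id`, `role`).
#' @param path File path.
#' @return `read_split` returns the split data.frame; `write_split` returns
#'   the path invisibly.
#' @export
write_split <- function(split, path) {
  .check_split(split)
  utils::write.csv(split[, c("id", "role")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("id", "role") %in% names(tab))) {
    stop("split file must have columns id,role")
  }
  .check_split(tab[, c("id", "role")])
}

#' Identity percentage between two splits
#'
#' The percentage of compounds holding a given role in both splits, relative
#' to the number holding that role in the first split (so the matrix of all
#' pairwise values is asymmetric in general).
#'
#' @param s1,s2 Split data.frames over the same compound ids.
#' @param role One of `"A"`, `"P"`, `"C"`, `"V"`.
#' @return Percentage rounded to one decimal.
#' @export
identity_percentage <- function(s1, s2, role) {
  .check_split(s1); .check_split(s2)
  role <- match.arg(role, .roles)
  if (!setequal(s1$id, s2$id)) {
    stop("splits cover different compound sets")
  }
  a <- s1$id[s1$role == role]
  b <- s2$id[s2$role == role]
  if (length(a) == 0L || length(b) == 0L) {
    stop("role ", role, " empty in one of the splits")
  }
  round(100 * length(intersect(a, b)) / length(a), 1L)
}

#' Pairwise identity-percentage matrix
#'
#' @param splits List of split data.frames over the same dataset.
#' @param role Role whose overlap is tabulated.
#' @return Square numeric matrix; the diagonal is 100 by construction.
#' @export
identity_matrix <- function(splits, role) {
  k <- length(splits)
  m <- matrix(NA_real_, k, k,
              dimnames = list(seq_len(k), seq_len(k)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- identity_percentage(splits[[i]], splits[[j]], role)
  }
  m
}
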