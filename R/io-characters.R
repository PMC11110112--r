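#' Construct a validated binary character matrix
#'
#' The central data container: an integer matrix with one row per binary
#' character (cognate class) and one column per language, each cell coding
#' presence (1) or absence (0) of the cognate in that language.  Characters
#' that are constant across all languages (all 0 or all 1) carry no
#' information under a Bernoulli-logit model with zero-mean effects and are
#' dropped with a warning.
#'
#' @param values matrix coercible to integer 0/1; rows = characters,
#'   columns = languages.
#' @param character_ids,language_ids optional id vectors; default to the
#'   dimnames of `values`.
#' @param drop_constant drop all-zero / all-one characters (default `TRUE`).
#' @return an integer matrix of class `"char_matrix"` with unique dimnames.
#' @export
character_matrix <- function(values, character_ids = rownames(values),
                             language_ids = colnames(values),
                             drop_constant = TRUE) {
  values <- as.matrix(values)
  if (is.null(character_ids)) {
    character_ids <- paste0("char_", seq_len(nrow(values)))
  }
  if (is.null(language_ids)) {
    language_ids <- paste0("lang_", seq_len(ncol(values)))
  }
  if (anyDuplicated(character_ids)) {
    stop("duplicate character ids: ",
         paste(unique(character_ids[duplicated(character_ids)]), collapse = ", "))
  }
  if (anyDuplicated(language_ids)) {
    stop("duplicate language ids: ",
         paste(unique(language_ids[duplicated(language_ids)]), collapse = ", "))
  }
  if (length(character_ids) != nrow(values) ||
      length(language_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell at character '%s', language '%s': %s",
                 character_ids[bad[1]], language_ids[bad[2]],
                 "missing data are not supported"))
  }
  if (!all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)))[1]
    idx <- arrayInd(bad, dim(values))
    stop(sprintf("cell at character '%s', language '%s' is not 0/1 (found '%s')",
                 character_ids[idx[1]], language_ids[idx[2]], values[bad]))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(character_ids, language_ids)
  if (ncol(values) < 3L) stop("need at least 3 languages, got ", ncol(values))
  if (drop_constant) {
    rs <- rowSums(values)
    const <- rs == 0L | rs == ncol(values)
    if (any(const)) {
      warning(sum(const), " constant character(s) dropped: ",
              paste(head(character_ids[const], 5), collapse = ", "),
              if (sum(const) > 5) ", ..." else "")
      values <- values[!const, , drop = FALSE]
    }
  }
  if (nrow(values) < 1L) stop("no informative characters remain")
  class(values) <- c("char_matrix", class(values))
  values
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d characters x %d languages\n", nrow(x), ncol(x)))
  y <- x
  class(y) <- "matrix"
  print(head(y, 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more characters)\n", sep = "")
  invisible(x)
}

#' Read a binary character matrix from CSV/TSV
#'
#' Expects a header row of language ids and a first column of character ids,
#' with 0/1 cells, e.g. rows = cognate classes, columns = languages.
#' Delimiter is inferred from the file extension (`.tsv`/`.tab` = tab,
#' otherwise comma) unless given.
#'
#' @param path file path.
#' @param sep field delimiter, or `NULL` to infer from the extension.
#' @param drop_constant drop constant characters with a warning.
#' @return a [character_matrix()].
#' @export
read_characters <- function(path, sep = NULL, drop_constant = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("character file needs a header and >= 1 data row")
  split1 <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(split1[[1]])
  langs <- header[-1]
  if (length(langs) < 1L) stop("header holds no language ids")
  n_field <- length(header)
  rows <- split1[-1]
  char_ids <- character(length(rows))
  vals <- matrix(NA_integer_, length(rows), length(langs))
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    if (length(f) != n_field) {
      stop(sprintf("row %d ('%s') has %d fields, expected %d",
                   i, f[1], length(f), n_field))
    }
    char_ids[i] <- f[1]
    cells <- f[-1]
    ok <- cells %in% c("0", "1")
    if (!all(ok)) {
      j <- which(!ok)[1]
      stop(sprintf("malformed cell at row '%s', column '%s': '%s' is not 0/1",
                   f[1], langs[j], cells[j]))
    }
    vals[i, ] <- as.integer(cells)
  }
  character_matrix(vals, character_ids = char_ids, language_ids = langs,
                   drop_constant = drop_constant)
}

#' Write a character matrix to CSV/TSV
#'
#' @param x a [character_matrix()].
#' @param path destination; delimiter inferred from extension as in
#'   [read_characters()].
#' @export
write_characters <- function(x, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  header <- paste(c("character", colnames(x)), collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], x[i, ]), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a language coordinate table
#'
#' CSV with columns `language`, `lat`, `lon` in decimal degrees (WGS84
#' assumed).  Latitudes must lie in \[-90, 90\], longitudes in (-180, 180\].
#'
#' @param path file path.
#' @return a `data.frame` of class `"coord_table"` with columns
#'   `language`, `lat`, `lon`.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("coordinate file is empty")
  coordinate_table(df)
}

#' Construct a validated coordinate table
#'
#' @param df data.frame with columns `language`, `lat`, `lon`.
#' @return the validated `data.frame`, classed `"coord_table"`.
#' @export
coordinate_table <- function(df) {
  need <- c("language", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop("coordinate table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$language <- as.character(df$language)
  if (anyDuplicated(df$language)) {
    stop("duplicate language in coordinates: ",
         df$language[duplicated(df$language)][1])
  }
  if (!all(is.finite(df$lat)) || !all(is.finite(df$lon))) {
    stop("non-finite coordinate values")
  }
  if (any(df$lat < -90 | df$lat > 90)) {
    stop("latitude outside [-90, 90] for: ",
         df$language[which(df$lat < -90 | df$lat > 90)][1])
  }
  if (any(df$lon <= -180 | df$lon > 180)) {
    stop("longitude outside (-180, 180] for: ",
         df$language[which(df$lon <= -180 | df$lon > 180)][1])
  }
  class(df) <- c("coord_table", "data.frame")
  df
}

#' Read a loanword flag table
#'
#' CSV with columns `character`, `is_loan` (logical or 0/1).  Used to compare
#' model-derived geographic conditioning scores against an external gold
#' standard of borrowings.
#'
#' @param path file path.
#' @param characters optional [character_matrix()]; if given, flags must be a
#'   subset of its character ids.
#' @return `data.frame` with columns `character` (character) and `is_loan`
#'   (logical).
#' @export
read_loan_flags <- function(path, characters = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("character", "is_loan") %in% names(df))) {
    stop("loan flag table needs columns: character, is_loan")
  }
  df$character <- as.character(df$character)
  if (is.character(df$is_loan)) {
    df$is_loan <- tolower(trimws(df$is_loan)) %in% c("true", "t", "1", "yes")
  } else {
    df$is_loan <- as.logical(df$is_loan)
  }
  if (anyNA(df$is_loan)) stop("unparseable is_loan values")
  if (anyDuplicated(df$character)) stop("duplicate character ids in loan flags")
  if (!is.null(characters) &&
      !all(df$character %in% rownames(characters))) {
    bad <- setdiff(df$character, rownames(characters))
    stop("loan flags reference unknown characters: ",
         paste(head(bad, 5), collapse = ", "))
  }
  df[, c("character", "is_loan")]
}

#' Write an analysis table as TSV
#'
#' All report tables (clade deltas, distance deltas, confound strengths,
#' character scores) are emitted as tab-separated text with a header row.
#'
#' @param table nonempty data.frame.
#' @param path destination path.
#' @export
write_report <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("report table must be a nonempty data.frame")
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
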