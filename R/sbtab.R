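#' Read SBtab-style TSV tables
#'
#' Parses the tab-separated SBtab dialect used for model exchange: each table
#' starts with a declaration line `!!SBtab TableName='...' TableType='...'`,
#' followed by a header row of `!`-prefixed column names and one row per
#' entry. A single file may hold several tables (separated by `!!SBtab`
#' lines); alternatively a directory of one-table `.tsv` files can be given.
#'
#' @param path Path to a multi-table TSV file or to a directory of `.tsv`
#'   files.
#' @return A named list of data frames (names are the `TableName`
#'   attributes); each data frame carries its declaration attributes in
#'   `attr(, "sbtab")`.
#' @export
read_sbtab <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    if (length(files) == 0L) {
      stopf("no .tsv files found in '%s'", path)
    }
    tabs <- do.call(c, lapply(files, read_sbtab))
    return(tabs)
  }
  if (!file.exists(path)) {
    stopf("file '%s' does not exist", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^%", lines)]
  starts <- grep("^!!SBtab", lines)
  if (length(starts) == 0L) {
    stopf("'%s' is not an SBtab file (no '!!SBtab' declaration line)", path)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  tabs <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    decl <- block[1L]
    attrs <- parse_sbtab_declaration(decl)
    if (length(block) < 2L) {
      stopf("SBtab table '%s' has no header row", attrs$TableName %||% "?")
    }
    header <- strsplit(block[2L], "\t", fixed = TRUE)[[1L]]
    header <- sub("^!", "", header)
    body <- block[-(1:2)]
    if (length(body) == 0L) {
      df <- as.data.frame(
        matrix(character(), nrow = 0, ncol = length(header),
               dimnames = list(NULL, header)),
        check.names = FALSE
      )
    } else {
      cells <- strsplit(body, "\t", fixed = TRUE)
      cells <- lapply(cells, function(r) {
        length(r) <- length(header)
        r
      })
      m <- do.call(rbind, cells)
      colnames(m) <- header
      df <- as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE)
    }
    attr(df, "sbtab") <- attrs
    nm <- attrs$TableName %||% sprintf("table%d", k)
    tabs[[nm]] <- df
  }
  tabs
}

parse_sbtab_declaration <- function(line) {
  pat <- "([A-Za-z]+)='([^']*)'"
  m <- gregexpr(pat, line)[[1L]]
  out <- list()
  if (m[1L] != -1L) {
    for (i in seq_along(m)) {
      frag <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1L)
      key <- sub(pat, "\\1", frag)
      val <- sub(pat, "\\2", frag)
      out[[key]] <- val
    }
  }
  out
}

#' Write SBtab-style TSV tables
#'
#' Inverse of [read_sbtab()]: writes a named list of data frames as a single
#' multi-table TSV file with `!!SBtab` declaration lines and `!`-prefixed
#' headers.
#'
#' @param tables Named list of data frames. Per-table declaration attributes
#'   are taken from `attr(, "sbtab")` when present.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbtab <- function(tables, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(tables)) {
    df <- tables[[nm]]
    attrs <- attr(df, "sbtab") %||% list()
    attrs$TableName <- attrs$TableName %||% nm
    attrs$TableType <- attrs$TableType %||% "Quantity"
    decl <- paste0(
      "!!SBtab ",
      paste(sprintf("%s='%s'", names(attrs), unlist(attrs)), collapse = " ")
    )
    writeLines(decl, con)
    writeLines(paste(paste0("!", colnames(df)), collapse = "\t"), con)
    if (nrow(df) > 0L) {
      rows <- apply(df, 1L, function(r) {
        r[is.na(r)] <- ""
        paste(r, collapse = "\t")
      })
      writeLines(rows, con)
    }
  }
  invisible(path)
}

#' Parse a reaction formula
#'
#' Understands the `"2 A + B <=> C"` grammar: two sides separated by `<=>`,
#' terms separated by `+`, each term an optional positive stoichiometric
#' coefficient followed by a compound identifier.
#'
#' @param formula Character scalar.
#' @return A list with data frames `substrates` and `products`, each with
#'   columns `id` and `coef` (positive).
#' @export
parse_reaction_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
    stopf("reaction formula must be a non-empty string")
  }
  sides <- strsplit(formula, "<=>", fixed = TRUE)[[1L]]
  if (length(sides) != 2L) {
    stopf("reaction formula '%s' must contain exactly one '<=>'", formula)
  }
  parse_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) {
      return(data.frame(id = character(), coef = numeric(),
                        stringsAsFactors = FALSE))
    }
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    parsed <- lapply(terms, function(t) {
      toks <- strsplit(t, "\\s+")[[1L]]
      if (length(toks) == 1L) {
        list(id = toks, coef = 1)
      } else if (length(toks) == 2L &&
                 grepl("^[0-9.]+$", toks[1L])) {
        list(id = toks[2L], coef = as.numeric(toks[1L]))
      } else {
        stopf("cannot parse reaction term '%s' in formula '%s'", t, formula)
      }
    })
    data.frame(
      id = vapply(parsed, `[[`, character(1L), "id"),
      coef = vapply(parsed, `[[`, numeric(1L), "coef"),
      stringsAsFactors = FALSE
    )
  }
  left <- parse_side(sides[1L])
  right <- parse_side(sides[2L])
  if (nrow(left) == 0L && nrow(right) == 0L) {
    stopf("reaction formula '%s' has no reactants", formula)
  }
  list(substrates = left, products = right)
}

# Convert a parsed value + unit string to the internal standard (mM, 1/s,
# kJ/mol for Gibbs energies, Da for masses). Unknown units raise an error.
convert_unit <- function(value, unit, quantity) {
  u <- tolower(trimws(unit %||% ""))
  if (u %in% c("", "dimensionless", "unitless", "1")) {
    return(value)
  }
  conc <- c("mm" = 1, "m" = 1000, "um" = 1e-3, "µm" = 1e-3, "nm" = 1e-6)
  if (u %in% names(conc)) {
    return(value * conc[[u]])
  }
  if (u %in% c("1/s", "s^-1", "s-1", "per second")) {
    return(value)
  }
  if (u %in% c("kj/mol", "kj mol^-1")) {
    return(value)
  }
  if (u %in% c("da", "dalton", "daltons")) {
    return(value)
  }
  if (u %in% c("kda")) {
    return(value * 1000)
  }
  if (u %in% c("mm/s", "mmol/l/s")) {
    return(value)
  }
  stopf("unknown unit '%s' for quantity '%s'", unit, quantity)
}
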