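#' Gene sets and GMT input/output
#'
#' A `gene_set` is a named collection of upper-case gene symbols with free-text
#' description (used here for literature provenance) and an optional subset of
#' *provisional* symbols — members whose inclusion is uncertain. Provisional
#' symbols are stored but excluded from the active membership unless asked for;
#' in GMT files they are written parenthesised, e.g. `(CCL3)`.
#'
#' @param name set name (no tab characters).
#' @param symbols character vector of gene symbols; upper-cased, must be
#'   non-empty, whitespace-free and unique after normalization.
#' @param description free-text description / citation tags.
#' @param provisional character vector of symbols flagged uncertain; need not
#'   be part of `symbols`.
#' @return An object of class `gene_set` with fields `name`, `symbols`,
#'   `description`, `provisional`.
#' @examples
#' gs <- gene_set("ddr", c("ATM", "NBN", "CHEK2"), "DNA damage response")
#' gs$symbols
#' @export
gene_set <- function(name, symbols, description = "", provisional = character(0)) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (grepl("\t", name)) stop2("gene set name must not contain tabs: ", name)
  symbols <- toupper(as.character(symbols))
  provisional <- toupper(as.character(provisional))
  if (length(symbols) == 0) stop2("gene set '", name, "' has no symbols")
  if (any(!nzchar(symbols)) || any(grepl("\\s", symbols))) {
    stop2("gene set '", name, "' has empty or whitespace-containing symbols")
  }
  if (anyDuplicated(symbols)) {
    stop2("gene set '", name, "' has duplicate symbols: ",
          paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  structure(list(name = name, symbols = symbols,
                 description = description, provisional = provisional),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$symbols), " symbols",
      if (length(x$provisional)) paste0(" (+", length(x$provisional), " provisional)"),
      "\n", sep = "")
  invisible(x)
}

#' Bundle gene sets into a collection
#'
#' @param sets list of [gene_set()] objects.
#' @return A named list of `gene_set`s with class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets = list()) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop2("duplicate set names: ",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(stats::setNames(sets, nm), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> with", length(x), "sets\n")
  for (s in x) {
    cat("  ", format(s$name, width = 12), length(s$symbols), "symbols\n")
  }
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>symbol...`. Symbols wrapped in parentheses are
#' read as provisional members and excluded from the active `symbols` slot.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop2("malformed GMT line ", i, " in '", path,
            "': expected >= 3 tab-separated fields, got ", length(fields))
    }
    syms <- fields[-(1:2)]
    prov <- grepl("^\\(.*\\)$", syms)
    sets[[i]] <- gene_set(name = fields[[1]],
                          symbols = sub("^\\((.*)\\)$", "\\1", syms),
                          description = fields[[2]],
                          provisional = sub("^\\((.*)\\)$", "\\1", syms[prov]))
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]: provisional members are written parenthesised so
#' that `read_gmt(write_gmt(x))` reproduces `x` exactly.
#'
#' @param sets a [gene_set_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(sets, function(s) {
    syms <- ifelse(s$symbols %in% s$provisional, paste0("(", s$symbols, ")"),
                   s$symbols)
    paste(c(s$name, s$description, syms), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Active membership of a gene set
#'
#' @param set a [gene_set()] or plain character vector.
#' @param include_provisional also include provisional members.
#' @return Character vector of symbols.
#' @export
set_symbols <- function(set, include_provisional = FALSE) {
  if (is.character(set)) return(toupper(set))
  stopifnot(inherits(set, "gene_set"))
  if (include_provisional) union(set$symbols, set$provisional)
  else setdiff(set$symbols, set$provisional)
}
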