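# Registry of pKa basis sets, terminal variants, correction tables and
# per-residue property scales. All numeric constants live in editable CSV
# files under inst/extdata/ and are validated at load; nothing is hard-coded
# in program logic, so every solver is parameterized by data.

the_registry <- new.env(parent = emptyenv())

IONIZABLE_SIDECHAINS <- c("C", "D", "E", "H", "K", "R", "Y")
BASIC_GROUPS <- c("K", "R", "H")

#' Construct and validate a pKa basis set
#'
#' A `pka_set` is a named basis of acid-dissociation constants: one pKa per
#' ionizable sidechain (any subset of C, D, E, H, K, R, Y) plus the two
#' terminal groups. A residue absent from `sidechain` is treated as
#' non-ionizable under the set.
#'
#' @param name Identifier of the set (stored lowercase).
#' @param sidechain Named numeric vector of sidechain pKas; names must be a
#'   subset of `C, D, E, H, K, R, Y`.
#' @param n_term,c_term Terminal pKas (pH units).
#' @param source Free-text citation for the values.
#' @return An object of class `pka_set`.
#' @examples
#' pka_set("toy", c(D = 4, K = 10.5), n_term = 9, c_term = 2.4)
#' @export
pka_set <- function(name, sidechain, n_term, c_term, source = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_validation("`name` must be a non-empty string.")
  }
  sidechain <- unlist(sidechain)
  if (length(sidechain) == 0L) {
    sidechain <- setNames(numeric(), character())
  } else {
    bad <- setdiff(names(sidechain), IONIZABLE_SIDECHAINS)
    if (length(bad) > 0L) {
      abort_validation(sprintf(
        "sidechain keys must be a subset of {%s}; offending: %s",
        paste(IONIZABLE_SIDECHAINS, collapse = ","),
        paste(bad, collapse = ", ")))
    }
    sidechain <- sidechain[order(names(sidechain))]
  }
  vals <- c(sidechain, n_term = n_term, c_term = c_term)
  check_pka_bounds(vals, name)
  structure(
    list(name = tolower(name),
         sidechain = sidechain,
         n_term = as.numeric(n_term),
         c_term = as.numeric(c_term),
         source = source),
    class = "pka_set")
}

check_pka_bounds <- function(vals, where) {
  if (any(!is.finite(vals))) {
    abort_validation(sprintf("Non-finite pKa value in '%s' (field %s).",
                             where, names(vals)[!is.finite(vals)][1]))
  }
  out <- vals <= 0 | vals >= 14
  if (any(out)) {
    abort_validation(sprintf(
      "pKa values must lie in the open interval (0, 14); '%s' violates this for field %s (value %s).",
      where, names(vals)[out][1], format(vals[out][1])))
  }
  invisible(TRUE)
}

#' @export
print.pka_set <- function(x, ...) {
  cat("<pka_set> ", x$name, "\n", sep = "")
  cat("  n_term ", format(x$n_term), ", c_term ", format(x$c_term), "\n",
      sep = "")
  if (length(x$sidechain) > 0L) {
    cat("  sidechain: ",
        paste(sprintf("%s=%.2f", names(x$sidechain), x$sidechain),
              collapse = ", "), "\n", sep = "")
  }
  if (nzchar(x$source)) cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}

# --- data-file parsing ------------------------------------------------------

read_source_comment <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) trimws(sub("^#\\s*source:\\s*", "", first)) else ""
}

read_table_file <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read one pKa set from its data file
#'
#' The file format is a CSV with columns `group` (one of `n_term`, `c_term`,
#' or an ionizable residue code) and `pka`, preceded by a `# source:` comment
#' line carrying the citation.
#'
#' @param path Path to the CSV file; the set name is the file stem.
#' @return A validated `pka_set`.
#' @export
read_pka_set <- function(path) {
  name <- tools::file_path_sans_ext(basename(path))
  df <- tryCatch(read_table_file(path), error = function(e) {
    abort_parse(sprintf("Malformed pKa set file '%s': %s", path,
                        conditionMessage(e)))
  })
  if (!all(c("group", "pka") %in% names(df))) {
    abort_parse(sprintf(
      "Malformed pKa set file '%s': missing column(s) %s.", path,
      paste(setdiff(c("group", "pka"), names(df)), collapse = ", ")))
  }
  if (anyDuplicated(df$group)) {
    abort_parse(sprintf("Malformed pKa set file '%s': duplicated group '%s'.",
                        path, df$group[duplicated(df$group)][1]))
  }
  known <- c("n_term", "c_term", IONIZABLE_SIDECHAINS)
  bad <- setdiff(df$group, known)
  if (length(bad) > 0L) {
    abort_parse(sprintf("Malformed pKa set file '%s': unknown group '%s'.",
                        path, bad[1]))
  }
  for (g in c("n_term", "c_term")) {
    if (!g %in% df$group) {
      abort_parse(sprintf("Malformed pKa set file '%s': missing entry '%s'.",
                          path, g))
    }
  }
  vals <- setNames(df$pka, df$group)
  pka_set(name,
          sidechain = vals[setdiff(names(vals), c("n_term", "c_term"))],
          n_term = vals[["n_term"]], c_term = vals[["c_term"]],
          source = read_source_comment(path))
}

#' Write a pKa set to its data-file format
#'
#' Inverse of [read_pka_set()]: serializing then re-reading yields an equal
#' set.
#'
#' @param set A `pka_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pka_set <- function(set, path) {
  stopifnot(inherits(set, "pka_set"))
  lines <- c(sprintf("# source: %s", set$source),
             "group,pka",
             sprintf("n_term,%s", format(set$n_term, digits = 15)),
             sprintf("c_term,%s", format(set$c_term, digits = 15)))
  if (length(set$sidechain) > 0L) {
    lines <- c(lines, sprintf("%s,%s", names(set$sidechain),
                              vapply(set$sidechain, format, "", digits = 15)))
  }
  writeLines(lines, path)
  invisible(path)
}

# --- terminal variants ------------------------------------------------------

#' Construct a terminal pKa variant for the position-dependent method
#'
#' A `terminal_variant` carries residue-dependent terminal pKas and optional
#' positional sidechain overrides, layered over a base `pka_set`. Lookups for
#' a (residue, context) pair fall back to the base set's internal value when
#' no positional entry exists.
#'
#' @param name Identifier.
#' @param n_term_by_residue,c_term_by_residue Named numeric vectors keyed by
#'   residue code; the key `default` supplies the fallback terminal pKa.
#' @param sidechain_positional Data frame with columns `residue`, `position`
#'   (`n-terminal`, `c-terminal` or `internal`) and `pka`; may be empty.
#' @param base_set Name of the base `pka_set` supplying internal sidechain
#'   pKas (default `"bjellqvist"`).
#' @param source Free-text citation.
#' @return An object of class `terminal_variant`.
#' @export
terminal_variant <- function(name, n_term_by_residue, c_term_by_residue,
                             sidechain_positional = NULL,
                             base_set = "bjellqvist", source = "") {
  n_term_by_residue <- unlist(n_term_by_residue)
  c_term_by_residue <- unlist(c_term_by_residue)
  if (!"default" %in% names(n_term_by_residue) ||
      !"default" %in% names(c_term_by_residue)) {
    abort_validation(
      "Terminal variants need a 'default' entry for both termini.")
  }
  check_pka_bounds(n_term_by_residue, name)
  check_pka_bounds(c_term_by_residue, name)
  if (is.null(sidechain_positional)) {
    sidechain_positional <- tibble(residue = character(),
                                   position = character(), pka = numeric())
  }
  sidechain_positional <- as_tibble(sidechain_positional)
  if (nrow(sidechain_positional) > 0L) {
    bad <- setdiff(sidechain_positional$position,
                   c("n-terminal", "c-terminal", "internal"))
    if (length(bad) > 0L) {
      abort_validation(sprintf("Unknown positional context '%s'.", bad[1]))
    }
    check_pka_bounds(setNames(sidechain_positional$pka,
                              sidechain_positional$residue), name)
  }
  structure(
    list(name = tolower(name),
         n_term_by_residue = n_term_by_residue,
         c_term_by_residue = c_term_by_residue,
         sidechain_positional = sidechain_positional,
         base_set = tolower(base_set),
         source = source),
    class = "terminal_variant")
}

read_terminal_variant <- function(path) {
  name <- tools::file_path_sans_ext(basename(path))
  df <- read_table_file(path)
  need <- c("context", "residue", "position", "pka")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("Malformed variant file '%s': missing column(s) %s.",
                        path, paste(setdiff(need, names(df)), collapse = ", ")))
  }
  pick <- function(ctx) {
    sub <- df[df$context == ctx, ]
    setNames(sub$pka, sub$residue)
  }
  sc <- df[df$context == "sidechain", c("residue", "position", "pka")]
  terminal_variant(name,
                   n_term_by_residue = pick("n_term"),
                   c_term_by_residue = pick("c_term"),
                   sidechain_positional = sc,
                   source = read_source_comment(path))
}

# --- correction tables ------------------------------------------------------

#' Construct a sequence-context correction table
#'
#' Correction tables hold additive pKa shifts keyed by (neighbor residue,
#' signed offset). The cofactor method uses a window of 3; the Branca method
#' a window of 6 plus an additive term keyed by the counts of Asp and Glu
#' sidechains. Entries with zero shift are equivalent to absent entries.
#'
#' @param method `"cofactor"` or `"branca"`.
#' @param entries Data frame with columns `residue`, `offset`, `delta`
#'   (pH units); may have zero rows.
#' @param carboxyl Optional data frame with columns `n_d`, `n_e`, `delta`
#'   (Branca only); patterns absent from the table contribute zero.
#' @param source Free-text citation.
#' @return An object of class `correction_table`.
#' @examples
#' correction_table("cofactor",
#'                  data.frame(residue = "K", offset = 1, delta = -0.2))
#' @export
correction_table <- function(method = c("cofactor", "branca"),
                             entries = NULL, carboxyl = NULL, source = "") {
  method <- match.arg(method)
  window <- if (method == "cofactor") 3L else 6L
  if (is.null(entries)) {
    entries <- tibble(residue = character(), offset = integer(),
                      delta = numeric())
  }
  entries <- as_tibble(entries)
  if (nrow(entries) > 0L) {
    if (any(entries$offset == 0L) || any(abs(entries$offset) > window)) {
      abort_validation(sprintf(
        "Correction offsets must be non-zero and |offset| <= %d for the %s method.",
        window, method))
    }
    entries <- entries[entries$delta != 0, ]
  }
  if (is.null(carboxyl)) {
    carboxyl <- tibble(n_d = integer(), n_e = integer(), delta = numeric())
  }
  carboxyl <- as_tibble(carboxyl)
  if (nrow(carboxyl) > 0L && method != "branca") {
    abort_validation("Carboxyl-count corrections apply to the branca method only.")
  }
  structure(
    list(method = method, window = window,
         entries = entries, carboxyl = carboxyl, source = source),
    class = "correction_table")
}

read_correction_table <- function(path, method) {
  df <- read_table_file(path)
  src <- read_source_comment(path)
  if (method == "branca") {
    nb <- df[df$kind == "neighbor", c("residue", "offset", "delta")]
    cx <- df[df$kind == "carboxyl", c("n_d", "n_e", "delta")]
    correction_table("branca", entries = nb, carboxyl = cx, source = src)
  } else {
    correction_table("cofactor", entries = df[, c("residue", "offset", "delta")],
                     source = src)
  }
}

# Fast lookup: named vector keyed "RESIDUE|OFFSET".
correction_lookup <- function(table) {
  if (nrow(table$entries) == 0L) return(numeric())
  setNames(table$entries$delta,
           paste(table$entries$residue, table$entries$offset, sep = "|"))
}

carboxyl_term <- function(table, n_d, n_e) {
  if (nrow(table$carboxyl) == 0L) return(0)
  hit <- table$carboxyl$n_d == n_d & table$carboxyl$n_e == n_e
  if (any(hit)) table$carboxyl$delta[hit][1] else 0
}

# --- registry ---------------------------------------------------------------

registry_populate <- function() {
  root <- system.file("extdata", package = "ampholyte")
  sets <- new.env(parent = emptyenv())
  for (f in list.files(file.path(root, "pka_sets"), full.names = TRUE)) {
    s <- read_pka_set(f)
    assign(s$name, s, envir = sets)
  }
  variants <- new.env(parent = emptyenv())
  for (f in list.files(file.path(root, "variants"), full.names = TRUE)) {
    v <- read_terminal_variant(f)
    assign(v$name, v, envir = variants)
  }
  the_registry$pka_sets <- sets
  the_registry$variants <- variants
  the_registry$corrections <- list(
    cofactor = read_correction_table(
      file.path(root, "corrections", "cofactor.csv"), "cofactor"),
    branca = read_correction_table(
      file.path(root, "corrections", "branca.csv"), "branca"))
  props <- list()
  for (f in list.files(file.path(root, "properties"), full.names = TRUE)) {
    df <- read_table_file(f)
    props[[tools::file_path_sans_ext(basename(f))]] <-
      setNames(df$value, df$residue)
  }
  the_registry$properties <- props
  the_registry$modification_pkas <- read_table_file(
    file.path(root, "modifications.csv"))
  invisible(NULL)
}

registry_sets <- function() {
  if (is.null(the_registry$pka_sets)) registry_populate()
  the_registry$pka_sets
}

#' Load every bundled pKa basis set
#'
#' Reads and validates all shipped sets (solomon, rodwell, lehninger,
#' grimsley, patrickios, thurlkill, toseland, sillero, emboss, and the
#' bjellqvist base set used by the terminal-variant method) directly from the
#' bundled data files, independent of any sets registered in the session.
#'
#' @return Named list of `pka_set` objects.
#' @examples
#' names(load_builtin_sets())
#' @export
load_builtin_sets <- function() {
  files <- list.files(system.file("extdata", "pka_sets",
                                  package = "ampholyte"),
                      full.names = TRUE)
  out <- lapply(files, read_pka_set)
  names(out) <- vapply(out, function(s) s$name, "")
  out[order(names(out))]
}

#' List the names of registered pKa sets
#' @return Character vector of set names.
#' @export
pka_set_names <- function() sort(ls(registry_sets()))

#' Retrieve a registered pKa set by name
#'
#' Lookup is case-insensitive. The returned object is a value copy; mutating
#' it does not affect the registry.
#'
#' @param name Set identifier.
#' @return A `pka_set`.
#' @examples
#' get_pka_set("emboss")
#' @export
get_pka_set <- function(name) {
  sets <- registry_sets()
  key <- tolower(name)
  if (!exists(key, envir = sets, inherits = FALSE)) {
    abort_lookup(sprintf(
      "Unknown pKa set '%s'. Registered sets: %s.", name,
      paste(sort(ls(sets)), collapse = ", ")))
  }
  get(key, envir = sets, inherits = FALSE)
}

#' Register a pKa set
#'
#' Adds a user-defined set to the in-session registry so every solver and the
#' benchmark grid can use it by name.
#'
#' @param set A `pka_set` (see [pka_set()]).
#' @param overwrite Allow replacing an existing set of the same name.
#' @return The registered set, invisibly.
#' @export
register_pka_set <- function(set, overwrite = FALSE) {
  if (!inherits(set, "pka_set")) {
    abort_validation("`set` must be a pka_set object.")
  }
  sets <- registry_sets()
  if (exists(set$name, envir = sets, inherits = FALSE) && !overwrite) {
    abort_validation(sprintf(
      "A pKa set named '%s' is already registered; pass overwrite = TRUE to replace it.",
      set$name))
  }
  assign(set$name, set, envir = sets)
  invisible(set)
}

#' Retrieve a terminal variant by name
#'
#' @param name One of `default`, `expasy`, `calibrated`, `skoog`, or a
#'   registered custom variant.
#' @return A `terminal_variant`.
#' @export
get_terminal_variant <- function(name) {
  if (inherits(name, "terminal_variant")) return(name)
  if (is.null(the_registry$variants)) registry_populate()
  key <- tolower(name)
  if (!exists(key, envir = the_registry$variants, inherits = FALSE)) {
    abort_lookup(sprintf(
      "Unknown terminal variant '%s'. Registered variants: %s.", name,
      paste(sort(ls(the_registry$variants)), collapse = ", ")))
  }
  get(key, envir = the_registry$variants, inherits = FALSE)
}

#' List registered terminal-variant names
#' @return Character vector.
#' @export
terminal_variant_names <- function() {
  if (is.null(the_registry$variants)) registry_populate()
  sort(ls(the_registry$variants))
}

#' Retrieve a shipped sequence-context correction table
#'
#' @param method `"cofactor"` or `"branca"`.
#' @return A `correction_table`.
#' @export
get_correction_table <- function(method = c("cofactor", "branca")) {
  method <- match.arg(method)
  if (is.null(the_registry$corrections)) registry_populate()
  the_registry$corrections[[method]]
}

#' Retrieve a bundled per-residue property scale
#'
#' @param name Scale identifier (e.g. `"hydropathy"`, `"residue_mass"`).
#' @return Named numeric vector over the 20 standard residues.
#' @export
get_property_table <- function(name) {
  if (is.null(the_registry$properties)) registry_populate()
  if (!name %in% names(the_registry$properties)) {
    abort_lookup(sprintf(
      "Unknown property table '%s'. Available: %s.", name,
      paste(names(the_registry$properties), collapse = ", ")))
  }
  the_registry$properties[[name]]
}

# Site pKas for a modification label, from the modifications data file.
modification_pkas <- function(label = "phospho") {
  if (is.null(the_registry$modification_pkas)) registry_populate()
  df <- the_registry$modification_pkas
  df[df$modification == label, c("pka", "polarity")]
}
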