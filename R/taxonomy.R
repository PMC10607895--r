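#' Four-level ingredient taxonomy
#'
#' An `ingredient_taxonomy` holds four ordered category registries (level 1 at
#' the top, level 4 at the leaves) together with single-parent links between
#' consecutive levels. Category ids are dense and 0-based within each level,
#' assigned in file order, so they double as classifier output indices.
#'
#' @param levels list of 4 character vectors of category names (level 1..4).
#' @param parents list of 3 integer vectors: `parents[[l]]` maps each level-
#'   `l+1` category id (0-based, position `id + 1`) to its level-`l` parent id.
#'
#' @param strict if `TRUE` (default) a tree truncated above level 4 is
#'   rejected; with `FALSE`, trailing empty levels are tolerated so partial
#'   trees (e.g. only levels 1--2 transcribed) can be inspected.
#' @return An object of class `ingredient_taxonomy` with elements `levels`,
#'   `parents` and `counts` (named `C1`..`C4`).
#' @export
ingredient_taxonomy <- function(levels, parents, strict = TRUE) {
  stopifnot(length(levels) == 4L, length(parents) == 3L)
  tax <- structure(
    list(
      levels  = lapply(levels, as.character),
      parents = lapply(parents, as.integer),
      counts  = stats::setNames(lengths(levels), paste0("C", 1:4))
    ),
    class = "ingredient_taxonomy"
  )
  rep <- validate_taxonomy(tax)
  if (!strict) {
    # tolerate a truncated tree: levels l..4 all empty
    n <- lengths(tax$levels)
    trailing <- if (any(n == 0L)) min(which(n == 0L)):4L else integer(0)
    if (all(n[trailing] == 0L))
      rep <- setdiff(rep, sprintf("level %d is empty", trailing))
  }
  if (length(rep) > 0L)
    stop("invalid taxonomy:\n", paste("-", rep, collapse = "\n"))
  tax
}

#' @export
print.ingredient_taxonomy <- function(x, ...) {
  cat("<ingredient_taxonomy> C =",
      paste0("(", paste(x$counts, collapse = ", "), ")"), "\n")
  for (l in 1:4) {
    nm <- x$levels[[l]]
    shown <- paste(utils::head(nm, 6L), collapse = ", ")
    if (length(nm) > 6L) shown <- paste0(shown, ", ...")
    cat(sprintf("  level %d (%d): %s\n", l, length(nm), shown))
  }
  invisible(x)
}

#' Validate an ingredient taxonomy
#'
#' Checks the structural invariants: four positive-size levels, unique names
#' within a level, and exactly one in-range parent for every category at
#' levels 2--4. Returns all violations rather than stopping at the first.
#'
#' @param tax object shaped like an [ingredient_taxonomy()] (class not required,
#'   so partially built structures can be inspected).
#' @return Character vector of human-readable violations; empty iff valid.
#' @export
validate_taxonomy <- function(tax) {
  rep <- character(0)
  if (!is.list(tax$levels) || length(tax$levels) != 4L)
    return("taxonomy must have exactly 4 levels")
  for (l in 1:4) {
    nm <- tax$levels[[l]]
    if (length(nm) < 1L)
      rep <- c(rep, sprintf("level %d is empty", l))
    dup <- unique(nm[duplicated(nm)])
    if (length(dup) > 0L)
      rep <- c(rep, sprintf("duplicate name at level %d: %s", l,
                            paste(dup, collapse = ", ")))
  }
  for (l in 2:4) {
    par <- tax$parents[[l - 1L]]
    nm <- tax$levels[[l]]
    if (length(par) != length(nm)) {
      rep <- c(rep, sprintf(
        "level %d has %d categories but %d parent links", l,
        length(nm), length(par)))
      next
    }
    bad <- which(is.na(par) | par < 0L | par >= length(tax$levels[[l - 1L]]))
    for (i in bad)
      rep <- c(rep, sprintf("category '%s' (level %d) has missing parent",
                            nm[i], l))
  }
  if (!is.null(tax$counts) &&
      !all(tax$counts == lengths(tax$levels)))
    rep <- c(rep, "counts C1..C4 do not match registry sizes")
  rep
}

#' Load a taxonomy from a flat edge list
#'
#' Reads the tree from a TSV (columns `level`, `name`, `parent`) or a JSON
#' array of objects with the same fields. Level-1 rows leave `parent` empty.
#' Ids are assigned 0-based per level in file order, making label indices
#' reproducible from the file alone.
#'
#' @param source path to a `.tsv`/`.txt` or `.json` file, or a data.frame with
#'   columns `level`, `name`, `parent`.
#' @param strict passed to [ingredient_taxonomy()]; with `FALSE`, a tree whose
#'   deepest levels are absent still loads (useful for inspecting partial
#'   transcriptions of the category standard).
#' @return A validated [ingredient_taxonomy()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("level\tname\tparent",
#'              "1\tCrop\t", "2\tFruits\tCrop",
#'              "3\tpome\tFruits", "4\tapple\tpome"), f)
#' tax <- load_taxonomy(f)
#' tax$counts
load_taxonomy <- function(source, strict = TRUE) {
  if (is.data.frame(source)) {
    df <- source
  } else {
    if (!file.exists(source)) stop("taxonomy file not found: ", source)
    if (grepl("\\.json$", source, ignore.case = TRUE)) {
      df <- jsonlite::fromJSON(source)
    } else {
      df <- utils::read.delim(source, stringsAsFactors = FALSE,
                              na.strings = character(0))
    }
  }
  need <- c("level", "name", "parent")
  if (!all(need %in% names(df)))
    stop("taxonomy source must have columns: ", paste(need, collapse = ", "))
  df$level <- as.integer(df$level)
  df$name <- as.character(df$name)
  df$parent <- as.character(df$parent)
  df$parent[is.na(df$parent)] <- ""
  if (any(is.na(df$level) | df$level < 1L | df$level > 4L))
    stop("taxonomy levels must be integers in 1..4")

  levels <- lapply(1:4, function(l) unique(df$name[df$level == l]))
  # duplicate rows for one (level, name) with different parents = multi-parent
  parents <- vector("list", 3L)
  for (l in 2:4) {
    nm <- levels[[l]]
    par <- integer(length(nm))
    for (i in seq_along(nm)) {
      p <- unique(df$parent[df$level == l & df$name == nm[i]])
      p <- p[p != ""]
      if (length(p) > 1L)
        stop(sprintf("category '%s' (level %d) has multiple parents: %s",
                     nm[i], l, paste(p, collapse = ", ")))
      if (length(p) == 0L)
        stop(sprintf("category '%s' (level %d) has no parent", nm[i], l))
      idx <- match(p, levels[[l - 1L]])
      if (is.na(idx))
        stop(sprintf("category '%s' (level %d) has orphan parent '%s'",
                     nm[i], l, p))
      par[i] <- idx - 1L
    }
    parents[[l - 1L]] <- par
  }
  ingredient_taxonomy(levels, parents, strict = strict)
}

#' Lift a leaf label to all four taxonomy levels
#'
#' Follows the single-parent chain upward from a level-4 (leaf) category,
#' producing the hierarchical label used by multi-level training.
#'
#' @param tax an [ingredient_taxonomy()].
#' @param leaf 0-based level-4 category id, or a leaf name.
#' @return A `hierarchical_label`: integer vector `c(y1, y2, y3, y4)` of
#'   0-based per-level ids, with per-level names attached.
#' @export
lift_label <- function(tax, leaf) {
  stopifnot(inherits(tax, "ingredient_taxonomy"))
  if (is.character(leaf)) {
    id <- match(leaf, tax$levels[[4]]) - 1L
    if (is.na(id)) stop("unknown leaf name: ", leaf)
    leaf <- id
  }
  leaf <- as.integer(leaf)
  if (is.na(leaf) || leaf < 0L || leaf >= tax$counts[["C4"]])
    stop("unknown level-4 id: ", leaf)
  y <- integer(4)
  y[4] <- leaf
  for (l in 3:1) y[l] <- tax$parents[[l]][y[l + 1L] + 1L]
  structure(stats::setNames(y, paste0("y", 1:4)),
            names_by_level = vapply(1:4, function(l)
              tax$levels[[l]][y[l] + 1L], character(1)),
            class = "hierarchical_label")
}

#' @export
print.hierarchical_label <- function(x, ...) {
  cat("<hierarchical_label>",
      paste(attr(x, "names_by_level"), collapse = " > "), "\n")
  invisible(x)
}
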