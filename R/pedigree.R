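#' Construct a pedigree of breeding lines
#'
#' Builds a validated, topologically ordered pedigree from line records.
#' Every known parent is guaranteed to appear before its offspring,
#' regardless of input order.  Parents that are referenced but have no
#' record of their own are materialized as founder records (both parents
#' unknown), because breeding pedigrees routinely cite base-population
#' clones without listing them.
#'
#' @param id character vector of line identifiers (non-empty, unique).
#' @param parent1,parent2 character vectors of parent identifiers;
#'   unknown-parent tokens (see `unknown`) and `NA` are normalized to
#'   unknown.
#' @param crossing_year optional integer vector of crossing years;
#'   `NA` allowed.
#' @param unknown character vector of tokens (case-insensitive) treated
#'   as "parent unknown" in addition to `NA`.
#'
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `id`, `parent1`, `parent2` (`NA` = unknown) and `crossing_year`,
#'   topologically ordered.
#' @seealso [read_pedigree()], [trace_pedigree()], [completeness()]
#' @export
pedigree <- function(id, parent1, parent2, crossing_year = NULL,
                     unknown = c("", "0", "na", "unknown")) {
  id <- as.character(id)
  if (anyNA(id) || any(!nzchar(id)))
    stop("line ids must be non-empty and non-missing")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate line id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  norm <- function(p) {
    p <- as.character(p)
    p[is.na(p) | tolower(trimws(p)) %in% tolower(unknown)] <- NA_character_
    p
  }
  parent1 <- norm(parent1)
  parent2 <- norm(parent2)
  if (any(!is.na(parent1) & parent1 == id) ||
      any(!is.na(parent2) & parent2 == id))
    stop("a line cannot be its own parent")
  if (is.null(crossing_year)) {
    crossing_year <- rep(NA_integer_, length(id))
  } else {
    crossing_year <- as.integer(crossing_year)
  }

  # materialize referenced-but-absent parents as founders
  referenced <- setdiff(unique(c(parent1, parent2)), c(id, NA_character_))
  if (length(referenced)) {
    message(length(referenced), " parent id(s) without a record; ",
            "inserted as founders")
    id <- c(id, referenced)
    parent1 <- c(parent1, rep(NA_character_, length(referenced)))
    parent2 <- c(parent2, rep(NA_character_, length(referenced)))
    crossing_year <- c(crossing_year, rep(NA_integer_, length(referenced)))
  }

  ped <- data.frame(id = id, parent1 = parent1, parent2 = parent2,
                    crossing_year = crossing_year,
                    stringsAsFactors = FALSE)
  ped <- ped[ped_toposort(ped), , drop = FALSE]
  rownames(ped) <- NULL

  # crossing year must not precede that of a known parent
  yr <- ped$crossing_year
  for (p in c("parent1", "parent2")) {
    py <- yr[match(ped[[p]], ped$id)]
    bad <- !is.na(yr) & !is.na(py) & yr < py
    if (any(bad))
      warning("crossing_year precedes a parent's for: ",
              paste(utils::head(ped$id[bad], 5L), collapse = ", "))
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; returns a permutation putting parents before offspring.
# Errors with one explicit cycle if the graph is not a DAG.
ped_toposort <- function(ped) {
  n <- nrow(ped)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(p1[j], p2[j])) {
      if (!is.na(p)) {
        indeg[j] <- indeg[j] + 1L
        kids[[p]] <- c(kids[[p]], j)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    cyc <- ped_find_cycle(ped, left, p1, p2)
    stop("pedigree contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  out
}

ped_find_cycle <- function(ped, left, p1, p2) {
  # walk parent links inside the unresolved subset until a repeat
  cur <- left[1L]
  seen <- integer(0)
  while (!(cur %in% seen)) {
    seen <- c(seen, cur)
    nxt <- c(p1[cur], p2[cur])
    nxt <- nxt[!is.na(nxt) & nxt %in% left]
    cur <- nxt[1L]
  }
  path <- seen[which(seen == cur):length(seen)]
  ped$id[c(path, cur)]
}

#' Read a pedigree from a CSV file
#'
#' The file must have a header with (possibly renamed) columns for the
#' line id and its two parents; a crossing-year column is optional.
#'
#' @param path path to a CSV file (UTF-8).
#' @param dialect named character vector mapping the canonical column
#'   names `id`, `parent1`, `parent2`, `crossing_year` to the column
#'   names used in the file.
#' @inheritParams pedigree
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path,
                          dialect = c(id = "id", parent1 = "parent1",
                                      parent2 = "parent2",
                                      crossing_year = "crossing_year"),
                          unknown = c("", "0", "na", "unknown")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "parent1", "parent2")
  cols <- dialect[need]
  if (any(!cols %in% names(df)))
    stop("missing column(s): ",
         paste(cols[!cols %in% names(df)], collapse = ", "))
  ycol <- dialect[["crossing_year"]]
  yr <- if (!is.na(ycol) && ycol %in% names(df))
    suppressWarnings(as.integer(df[[ycol]])) else NULL
  pedigree(df[[cols[["id"]]]], df[[cols[["parent1"]]]],
           df[[cols[["parent2"]]]], yr, unknown = unknown)
}

#' Write a pedigree to CSV
#'
#' Emits the ordered pedigree in the canonical
#' `id,parent1,parent2,crossing_year` dialect (unknown parents as empty
#' cells).
#'
#' @param ped a [pedigree].
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  out$parent1[is.na(out$parent1)] <- ""
  out$parent2[is.na(out$parent2)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Trace the ancestry of focal lines
#'
#' Returns the sub-pedigree holding the focal lines and all of their
#' ancestors, re-ordered topologically.  Used to restrict a large
#' program pedigree to the lines carrying phenotypes before building
#' relationship matrices.
#'
#' @param ped a [pedigree].
#' @param focal_ids character vector of line ids present in `ped`.
#' @return A [pedigree] containing the ancestor closure of `focal_ids`.
#' @export
trace_pedigree <- function(ped, focal_ids) {
  stopifnot(inherits(ped, "pedigree"))
  focal_ids <- unique(as.character(focal_ids))
  miss <- setdiff(focal_ids, ped$id)
  if (length(miss))
    stop("focal id(s) not in pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  keep <- logical(nrow(ped))
  keep[match(focal_ids, ped$id)] <- TRUE
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  # ped is topologically ordered, so one reverse sweep closes ancestry
  for (j in rev(seq_len(nrow(ped)))) {
    if (keep[j]) {
      if (!is.na(p1[j])) keep[p1[j]] <- TRUE
      if (!is.na(p2[j])) keep[p2[j]] <- TRUE
    }
  }
  out <- ped[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Pedigree completeness
#'
#' Completeness counts known ancestral generations per line, fractional
#' for ragged pedigrees: `C(i)` is the sum over known parents `p` of
#' `(1 + C(p)) / 2`.  A line with both parents known founders scores 1;
#' with all four grandparents known founders it scores 2; a single known
#' founder parent scores 0.5.
#'
#' @param ped a [pedigree].
#' @return An object of class `completeness_summary`: list with
#'   `per_id` (named numeric), `mean`, `max`, and
#'   `frac_unknown_parents` (share of lines with >= 1 unknown parent).
#' @export
completeness <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  C <- numeric(n)
  for (j in seq_len(n)) {     # topological order: parents already done
    v <- 0
    if (!is.na(p1[j])) v <- v + (1 + C[p1[j]]) / 2
    if (!is.na(p2[j])) v <- v + (1 + C[p2[j]]) / 2
    C[j] <- v
  }
  names(C) <- ped$id
  res <- list(per_id = C, mean = mean(C), max = max(C),
              frac_unknown_parents = mean(is.na(p1) | is.na(p2)))
  class(res) <- "completeness_summary"
  res
}

#' @export
print.completeness_summary <- function(x, ...) {
  cat("Pedigree completeness over", length(x$per_id), "lines\n")
  cat(sprintf("  mean %.2f, max %.2f, %.1f%% of lines with an unknown parent\n",
              x$mean, x$max, 100 * x$frac_unknown_parents))
  invisible(x)
}

#' Partition lines into breeding cycles by crossing year
#'
#' Lines sharing a crossing year form one breeding cycle, the unit of
#' leave-one-breeding-cycle-out cross-validation.  Records without a
#' crossing year are dropped with a warning.
#'
#' @param ped a [pedigree].
#' @return Named list (one element per year, ascending) of character
#'   vectors of line ids.
#' @export
breeding_cycles <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  has <- !is.na(ped$crossing_year)
  if (!any(has)) stop("no crossing years recorded in pedigree")
  if (!all(has))
    warning(sum(!has), " record(s) without crossing_year excluded ",
            "from cycles")
  split(ped$id[has], ped$crossing_year[has])
}

#' @export
print.pedigree <- function(x, n = 6L, ...) {
  cat("Tetraploid breeding pedigree:", nrow(x), "lines")
  founders <- sum(is.na(x$parent1) & is.na(x$parent2))
  cat(" (", founders, " founders)\n", sep = "")
  if (any(!is.na(x$crossing_year)))
    cat("  crossing years ", min(x$crossing_year, na.rm = TRUE), "-",
        max(x$crossing_year, na.rm = TRUE), "\n", sep = "")
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}
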