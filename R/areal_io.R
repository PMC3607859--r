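# Reading, validating and writing the areal data structures used throughout:
# an area table (one row per areal unit) and a neighbour-list adjacency.

#' @importFrom utils read.csv write.csv
NULL

.component_cols <- c("comp_no_water", "comp_no_toilet", "comp_no_refuse",
                     "comp_no_electricity", "comp_no_schooling",
                     "comp_informal", "comp_health_ratio")

.required_cols <- c("area_id", "province", "population", "deaths",
                    .component_cols, "hiv_prev", "density_class")

.density_levels <- c("low_medium", "high_nonmetro", "high_metro")

#' Column schema of an area table
#'
#' Returns the column names an area table must (and may) carry. Required
#' columns are the unit identifier and province label, population and death
#' counts, the seven service (non-)delivery components, antenatal HIV
#' seroprevalence (percent) and the three-level density/metro class. A
#' `gini` column in `[0, 1]` is optional when an `incomes` column (per-unit
#' household incomes joined by `";"`) is present, from which the Gini
#' coefficient can be computed.
#'
#' @return A list with elements `required`, `components` and `optional`.
#' @export
area_table_schema <- function() {
  list(required = .required_cols,
       components = .component_cols,
       optional = c("gini", "incomes"))
}

#' Validate an in-memory area table
#'
#' Enforces the row-level invariants: unique `area_id`, `deaths <=
#' population`, non-negative counts, component proportions in `[0, 1]`
#' (`comp_health_ratio` may be any non-negative real: it is a population per
#' health facility), `hiv_prev` in `[0, 100]`, known `density_class`
#' labels, and `gini` present or computable from `incomes`.
#'
#' @param table A data frame following [area_table_schema()].
#' @return The table, invisibly, with `incomes` parsed to a list column.
#' @export
as_area_table <- function(table) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(.required_cols, names(table))
  if (length(missing) > 0L) {
    stop("area table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) < 1L) stop("area table must have at least one row", call. = FALSE)
  table$area_id <- as.character(table$area_id)
  dup <- table$area_id[duplicated(table$area_id)]
  if (length(dup) > 0L) {
    stop("duplicated area_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(table$population < 0) || any(table$deaths < 0)) {
    stop("population and deaths must be non-negative", call. = FALSE)
  }
  bad <- which(table$deaths > table$population)
  if (length(bad) > 0L) {
    stop("deaths exceed population for area_id: ",
         paste(table$area_id[bad], collapse = ", "), call. = FALSE)
  }
  if (sum(table$population) <= 0) stop("total population must be positive", call. = FALSE)
  for (cc in setdiff(.component_cols, "comp_health_ratio")) {
    v <- table[[cc]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      stop("column ", cc, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(table$comp_health_ratio < 0)) {
    stop("comp_health_ratio must be non-negative", call. = FALSE)
  }
  if (any(table$hiv_prev < 0 | table$hiv_prev > 100)) {
    stop("hiv_prev must be a percentage in [0, 100]", call. = FALSE)
  }
  if (!all(table$density_class %in% .density_levels)) {
    stop("density_class must be one of: ", paste(.density_levels, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(table$incomes) && !is.list(table$incomes)) {
    table$incomes <- lapply(strsplit(as.character(table$incomes), ";", fixed = TRUE),
                            function(s) as.numeric(s[nzchar(s)]))
  }
  has_gini <- !is.null(table$gini) && all(is.finite(table$gini))
  if (has_gini && any(table$gini < 0 | table$gini > 1)) {
    stop("gini must lie in [0, 1]", call. = FALSE)
  }
  if (!has_gini) {
    if (is.null(table$incomes)) {
      stop("gini column absent and no incomes supplied to compute it from",
           call. = FALSE)
    }
    n_inc <- vapply(table$incomes, length, integer(1))
    need <- if (is.null(table$gini)) rep(TRUE, nrow(table)) else !is.finite(table$gini)
    if (any(need & n_inc < 1L)) {
      stop("gini missing and incomes empty for area_id: ",
           paste(table$area_id[need & n_inc < 1L], collapse = ", "), call. = FALSE)
    }
  }
  class(table) <- unique(c("area_table", class(table)))
  invisible(table)
}

#' Read an area table from delimited text
#'
#' Reads a comma-delimited UTF-8 file whose header follows
#' [area_table_schema()] and enforces all row invariants. Row order is
#' preserved: the file's row order defines the unit index `i` used by every
#' vector downstream.
#'
#' @param path Path to a CSV file.
#' @return A validated `area_table` data frame.
#' @export
read_area_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
  as_area_table(raw)
}

#' Write an area table to delimited text
#'
#' Inverse of [read_area_table()]: a write followed by a read reproduces
#' identical field values. List-valued `incomes` are serialized joined by
#' `";"`.
#'
#' @param table A validated area table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(table, path) {
  out <- as.data.frame(table)
  if (!is.null(out$incomes) && is.list(out$incomes)) {
    out$incomes <- vapply(out$incomes, function(x)
      paste(format(x, scientific = FALSE, trim = TRUE), collapse = ";"), character(1))
  }
  class(out) <- "data.frame"
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct an adjacency object from neighbour lists
#'
#' @param nb Named list: for each `area_id`, a character vector of
#'   neighbouring `area_id`s. Symmetrized if needed (with a warning).
#' @return An `adjacency` object: list with `ids`, `nb` (named list) and
#'   `num_neighbours`.
#' @export
adjacency <- function(nb) {
  ids <- names(nb)
  if (is.null(ids) || any(!nzchar(ids))) stop("nb must be a fully named list", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicated area ids in neighbour list", call. = FALSE)
  nb <- lapply(nb, function(x) unique(as.character(x)))
  # drop self-loops
  nb <- mapply(function(id, x) setdiff(x, id), ids, nb, SIMPLIFY = FALSE)
  unknown <- setdiff(unique(unlist(nb)), ids)
  if (length(unknown) > 0L) {
    stop("neighbour id(s) not present as units: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  asym <- FALSE
  for (i in ids) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]])) {
        nb[[j]] <- c(nb[[j]], i)
        asym <- TRUE
      }
    }
  }
  if (asym) warning("asymmetric adjacency listing repaired by symmetrization")
  nn <- vapply(nb, length, integer(1))
  if (any(nn == 0L)) {
    warning("isolated unit(s) with zero neighbours: ",
            paste(ids[nn == 0L], collapse = ", "))
  }
  structure(list(ids = ids, nb = nb, num_neighbours = nn), class = "adjacency")
}

#' Read a GAL neighbour-list file
#'
#' Parses the GAL areal-adjacency exchange format: a header line whose last
#' field is the number of units, then for each unit a line `"<id> <k>"`
#' followed by a line of `k` neighbour ids. Asymmetric listings are repaired
#' by symmetrization with a warning; isolated units are permitted but
#' flagged.
#'
#' @param path Path to a GAL file.
#' @return An `adjacency` object.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty GAL file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(hdr[[length(hdr)]]))
  if (length(hdr) > 1L) {
    # spdep-style header "0 n shapefile region_id": n is the second field
    n2 <- suppressWarnings(as.integer(hdr[[2]]))
    if (!is.na(n2)) n <- n2
  }
  if (is.na(n) || n < 1L) stop("invalid GAL header: ", lines[[1]], call. = FALSE)
  nb <- vector("list", n)
  ids <- character(n)
  pos <- 2L
  for (u in seq_len(n)) {
    if (pos > length(lines)) stop("truncated GAL file: ", path, call. = FALSE)
    rec <- strsplit(trimws(lines[[pos]]), "[[:space:]]+")[[1]]
    if (length(rec) != 2L) stop("malformed GAL record line: ", lines[[pos]], call. = FALSE)
    ids[u] <- rec[[1]]
    k <- suppressWarnings(as.integer(rec[[2]]))
    if (is.na(k) || k < 0L) stop("malformed neighbour count in: ", lines[[pos]], call. = FALSE)
    pos <- pos + 1L
    if (k == 0L) {
      nb[[u]] <- character(0)
    } else {
      if (pos > length(lines)) stop("truncated GAL file: ", path, call. = FALSE)
      nbr <- strsplit(trimws(lines[[pos]]), "[[:space:]]+")[[1]]
      if (length(nbr) != k) {
        stop("unit ", ids[u], " declares ", k, " neighbours but lists ",
             length(nbr), call. = FALSE)
      }
      nb[[u]] <- nbr
      pos <- pos + 1L
    }
  }
  names(nb) <- ids
  adjacency(nb)
}

#' Write an adjacency object as a GAL file
#'
#' @param adj An `adjacency` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  out <- character(0)
  out <- c(out, as.character(length(adj$ids)))
  for (id in adj$ids) {
    out <- c(out, paste(id, length(adj$nb[[id]])))
    if (length(adj$nb[[id]]) > 0L) out <- c(out, paste(adj$nb[[id]], collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Cross-validate an area table against an adjacency
#'
#' Produces a findings report rather than raising: id mismatches in either
#' direction, isolated (zero-neighbour) units, and zero-population units.
#' The boolean `pass` flag is `TRUE` only when no finding is present
#' (isolated units are reported but do not fail validation: the model layer
#' decides their treatment).
#'
#' @param table A validated area table.
#' @param adj An `adjacency` object.
#' @return A `validation_report` list with `pass`, `missing_in_adjacency`,
#'   `missing_in_table`, `isolated_units`, `zero_population_units`.
#' @export
validate_areal <- function(table, adj) {
  stopifnot(inherits(adj, "adjacency"))
  tab_ids <- as.character(table$area_id)
  rep <- list(
    missing_in_adjacency = setdiff(tab_ids, adj$ids),
    missing_in_table = setdiff(adj$ids, tab_ids),
    isolated_units = adj$ids[adj$num_neighbours == 0L],
    zero_population_units = tab_ids[table$population == 0]
  )
  rep$pass <- length(rep$missing_in_adjacency) == 0L &&
    length(rep$missing_in_table) == 0L &&
    length(rep$zero_population_units) == 0L
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("areal validation:", if (x$pass) "PASS" else "FAIL", "\n")
  for (f in c("missing_in_adjacency", "missing_in_table",
              "isolated_units", "zero_population_units")) {
    if (length(x[[f]]) > 0L) {
      cat("  ", f, ": ", paste(x[[f]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

# Dense symmetric 0/1 neighbour matrix in table/id order (internal).
adjacency_matrix <- function(adj, ids = adj$ids) {
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- match(adj$ids, ids)
  for (k in seq_along(adj$ids)) {
    i <- pos[k]
    if (is.na(i)) next
    j <- match(adj$nb[[k]], ids)
    j <- j[!is.na(j)]
    W[i, j] <- 1
  }
  W
}
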