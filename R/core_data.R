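#' Plot grid definition
#'
#' Defines the quadrat lattice for a rectangular forest dynamics plot.
#' Coordinates are 0-based and half-open: a point belongs to the plot iff
#' `0 <= x < plot_width` and `0 <= y < plot_height`, and quadrat cells are
#' `[k*s, (k+1)*s)`.  Quadrats are indexed row-major from the plot origin:
#' linear id `= qx + n_qx * qy` with 0-based column `qx` and row `qy`.
#'
#' @param plot_width,plot_height plot dimensions in metres.
#' @param quadrat_size quadrat edge length in metres (default 20).
#' @return An object of class `plot_grid` with elements `plot_width`,
#'   `plot_height`, `quadrat_size`, `n_qx`, `n_qy`, `n_quadrats`.
#' @examples
#' g <- plot_grid(400, 500)   # the canonical 20-ha layout: 500 quadrats
#' g$n_quadrats
#' @export
plot_grid <- function(plot_width, plot_height, quadrat_size = 20) {
  stopifnot(is.numeric(plot_width), plot_width > 0,
            is.numeric(plot_height), plot_height > 0,
            is.numeric(quadrat_size), quadrat_size > 0)
  nx <- plot_width / quadrat_size
  ny <- plot_height / quadrat_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("plot dimensions (", plot_width, " x ", plot_height,
         ") are not exact multiples of quadrat_size = ", quadrat_size)
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  structure(list(plot_width = plot_width, plot_height = plot_height,
                 quadrat_size = quadrat_size,
                 n_qx = nx, n_qy = ny, n_quadrats = nx * ny),
            class = "plot_grid")
}

#' @export
print.plot_grid <- function(x, ...) {
  cat(sprintf("plot_grid: %g m x %g m, %g m quadrats (%d x %d = %d quadrats)\n",
              x$plot_width, x$plot_height, x$quadrat_size,
              x$n_qx, x$n_qy, x$n_quadrats))
  invisible(x)
}

#' Quadrat id to (column, row) and back
#'
#' @param grid a [plot_grid()].
#' @param quadrat_id 0-based linear quadrat id(s).
#' @return `quadrat_rowcol`: data.frame with `quadrat_id`, `qx`, `qy`
#'   (0-based).  `quadrat_centers`: data.frame with `quadrat_id`, `x`, `y`
#'   (quadrat centre coordinates in metres).
#' @export
quadrat_rowcol <- function(grid, quadrat_id = seq_len(grid$n_quadrats) - 1L) {
  stopifnot(inherits(grid, "plot_grid"))
  id <- as.integer(quadrat_id)
  if (any(id < 0L | id >= grid$n_quadrats)) stop("quadrat_id out of range")
  data.frame(quadrat_id = id,
             qx = id %% grid$n_qx,
             qy = id %/% grid$n_qx)
}

#' @rdname quadrat_rowcol
#' @export
quadrat_centers <- function(grid) {
  rc <- quadrat_rowcol(grid)
  s <- grid$quadrat_size
  data.frame(quadrat_id = rc$quadrat_id,
             x = (rc$qx + 0.5) * s,
             y = (rc$qy + 0.5) * s)
}

# required columns of the two census tables
.stem_cols  <- c("stem_id", "x", "y", "species_id", "dbh")
.trait_cols <- c("species_id", "la", "sla", "ldmc", "wd", "max_dbh")

#' Read and validate a stem table
#'
#' Reads a delimited stem census (`stem_id,x,y,species_id,dbh`; DBH in cm,
#' coordinates in m) and validates it against the plot geometry and the
#' census protocol.  Rows failing validation are dropped and itemised in the
#' `"validation"` attribute of the result; a warning summarises the drops.
#' Validation rules: coordinates inside the half-open plot rectangle,
#' numeric `dbh >= 1` cm (census threshold), non-empty `species_id`.
#'
#' @param path path to a CSV file with a header row.
#' @param grid a [plot_grid()] giving the plot bounds.
#' @return A validated `data.frame` (classed `stem_table`) with attribute
#'   `"validation"`: a data.frame of rejected rows (`stem_id`, `reason`).
#' @seealso [validate_stem_table()] for validating an in-memory table.
#' @export
read_stem_table <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.stem_cols, names(df))
  if (length(missing) > 0)
    stop("stem table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  validate_stem_table(df, grid)
}

#' @rdname read_stem_table
#' @param stems a data.frame with the stem-table columns.
#' @export
validate_stem_table <- function(stems, grid) {
  stopifnot(inherits(grid, "plot_grid"))
  missing <- setdiff(.stem_cols, names(stems))
  if (length(missing) > 0)
    stop("stem table lacks required column(s): ", paste(missing, collapse = ", "))
  stems <- stems[, .stem_cols]
  id <- as.character(stems$stem_id)
  x <- suppressWarnings(as.numeric(stems$x))
  y <- suppressWarnings(as.numeric(stems$y))
  dbh <- suppressWarnings(as.numeric(stems$dbh))
  sp <- as.character(stems$species_id)

  reason <- rep(NA_character_, nrow(stems))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(x) | is.na(y), "non-numeric coordinate")
  reason <- flag(!is.na(x) & !is.na(y) &
                   (x < 0 | x >= grid$plot_width |
                    y < 0 | y >= grid$plot_height), "coordinate out of bounds")
  reason <- flag(is.na(dbh), "non-numeric dbh")
  reason <- flag(!is.na(dbh) & dbh < 1, "below census threshold")
  reason <- flag(is.na(sp) | sp == "", "empty species_id")

  bad <- !is.na(reason)
  report <- data.frame(stem_id = id[bad], reason = reason[bad],
                       stringsAsFactors = FALSE)
  if (nrow(report) > 0) {
    tab <- table(report$reason)
    warning(sum(bad), " stem row(s) rejected: ",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "))
  }
  out <- data.frame(stem_id = id[!bad], x = x[!bad], y = y[!bad],
                    species_id = sp[!bad], dbh = dbh[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "validation") <- report
  class(out) <- c("stem_table", "data.frame")
  out
}

#' Read and validate a species trait table
#'
#' Columns: `species_id,la,sla,ldmc,wd,max_dbh` with LA in cm^2, SLA in
#' cm^2/g, LDMC in g/g, WD in g/cm^3 and maximum DBH in cm.  All trait
#' values must be positive, LDMC at most 1, one row per species.
#'
#' @inheritParams read_stem_table
#' @return A validated `data.frame` (classed `trait_table`).
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(df)
}

#' @rdname read_trait_table
#' @param traits a data.frame with the trait-table columns.
#' @export
validate_trait_table <- function(traits) {
  missing <- setdiff(.trait_cols, names(traits))
  if (length(missing) > 0)
    stop("trait table lacks required column(s): ", paste(missing, collapse = ", "))
  traits <- traits[, .trait_cols]
  traits$species_id <- as.character(traits$species_id)
  if (anyDuplicated(traits$species_id))
    stop("trait table has duplicated species_id: ",
         paste(unique(traits$species_id[duplicated(traits$species_id)]),
               collapse = ", "))
  num <- c("la", "sla", "ldmc", "wd", "max_dbh")
  for (v in num) {
    traits[[v]] <- as.numeric(traits[[v]])
    if (any(!is.finite(traits[[v]])) || any(traits[[v]] <= 0))
      stop("trait '", v, "' must be finite and > 0 for all species")
  }
  if (any(traits$ldmc > 1)) stop("ldmc must be <= 1 (g dry per g fresh)")
  class(traits) <- c("trait_table", "data.frame")
  traits
}

#' Assign stems to quadrats
#'
#' Adds 0-based `qx`, `qy` and linear `quadrat_id = qx + n_qx * qy` columns
#' using the half-open cell convention `[k*s, (k+1)*s)`.
#'
#' @param stems a stem table with in-bounds `x`, `y`.
#' @param grid a [plot_grid()].
#' @return `stems` with `qx`, `qy`, `quadrat_id` columns appended.
#' @export
assign_quadrats <- function(stems, grid) {
  stopifnot(inherits(grid, "plot_grid"))
  oob <- stems$x < 0 | stems$x >= grid$plot_width |
         stems$y < 0 | stems$y >= grid$plot_height
  if (any(oob))
    stop("stem(s) out of plot bounds: ",
         paste(utils::head(stems$stem_id[oob], 5), collapse = ", "),
         if (sum(oob) > 5) sprintf(" (and %d more)", sum(oob) - 5) else "")
  s <- grid$quadrat_size
  stems$qx <- as.integer(floor(stems$x / s))
  stems$qy <- as.integer(floor(stems$y / s))
  stems$quadrat_id <- stems$qx + grid$n_qx * stems$qy
  stems
}

#' Quadrat-by-species abundance matrix
#'
#' Entry (q, s) is the number of stems of species s in quadrat q.  All
#' quadrats of the grid are retained as rows (empty quadrats give all-zero
#' rows); the grand total equals the number of stems.
#'
#' @param stems a stem table carrying `quadrat_id` (see [assign_quadrats()]).
#' @param grid a [plot_grid()].
#' @param species optional character vector fixing the column set and order;
#'   defaults to the sorted species observed in `stems`.
#' @return An integer matrix with rownames `0 ... n_quadrats-1` and species
#'   colnames.
#' @export
community_matrix <- function(stems, grid, species = NULL) {
  stopifnot(inherits(grid, "plot_grid"))
  if (is.null(stems$quadrat_id))
    stop("stems lack quadrat_id; call assign_quadrats() first")
  if (is.null(species)) species <- sort(unique(as.character(stems$species_id)))
  q <- factor(stems$quadrat_id, levels = seq_len(grid$n_quadrats) - 1L)
  s <- factor(as.character(stems$species_id), levels = species)
  m <- table(q, s)
  out <- matrix(as.integer(m), nrow = grid$n_quadrats,
                dimnames = list(rownames(m), colnames(m)))
  out
}

#' Write census tables back to CSV
#'
#' Plain-text writers matching the schemas of [read_stem_table()] and
#' [read_trait_table()]; `read(write(x))` round-trips exactly.
#'
#' @param x a stem or trait table.
#' @param path output CSV path.
#' @export
write_stem_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, .stem_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_stem_table
#' @export
write_trait_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, .trait_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
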