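# Plain-text self-describing array container: a single file whose first
# line is a '#' comment carrying a JSON metadata object (axis spacing,
# origin, units, provenance), followed by the matrix as tab-separated
# values (rows = lateral index, columns = depth index).

#' Write / read a 2-D field with metadata
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param meta Named list of metadata (must be JSON-representable); the cell
#'   size and axis convention belong here.
#' @return \code{write_grid_array}: the path, invisibly;
#'   \code{read_grid_array}: a list with \code{data} (matrix) and
#'   \code{meta}.
#' @export
write_grid_array <- function(m, path, meta = list()) {
  stopifnot(is.matrix(m))
  meta$dim <- dim(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                          digits = NA)), con)
  write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_array
#' @export
read_grid_array <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) stop("not a grid-array file: ", path,
                                    call. = FALSE)
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  m <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  if (!is.null(meta$dim) && !all(dim(m) == meta$dim)) {
    stop("grid-array dimensions do not match metadata in ", path,
         call. = FALSE)
  }
  list(data = m, meta = meta)
}

#' Write probe traces as delimited text
#'
#' One row per time sample: \code{time_s}, then one temperature column per
#' probe trace.
#'
#' @param history A \code{thermal_history}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_traces <- function(history, path) {
  stopifnot(inherits(history, "thermal_history"))
  d <- data.frame(time_s = history$times,
                  T_epidermis_C = history$epidermal_trace,
                  T_follicle_C = history$follicle_trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# category=%s baseline_C=%g", history$category,
                     history$baseline), con)
  write.table(format(d, digits = 10, trim = TRUE), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
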