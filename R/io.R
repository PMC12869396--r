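#' Write / read a gridded field as self-describing flat text
#'
#' Plain-text container: `#`-prefixed header lines give the grid origin,
#' spacing, shape and prior, followed by the value matrix (one grid row
#' per line, x varying across lines).
#'
#' @param field A [likelihood_field()].
#' @param path Output path.
#' @return `write_field` returns `path` invisibly; `read_field` returns a
#'   `likelihood_field` (its parametric provenance, if any, is restored
#'   from the header).
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "likelihood_field"))
  hdr <- c(
    sprintf("# origin %.15g %.15g", field$x[1L], field$y[1L]),
    sprintf("# spacing %.15g %.15g", field$hx, field$hy),
    sprintf("# shape %d %d", length(field$x), length(field$y)),
    sprintf("# prior %.15g %.15g %.15g %.15g",
            field$prior[1L], field$prior[2L], field$prior[3L], field$prior[4L]))
  if (!is.null(field$params))
    hdr <- c(hdr, sprintf("# params %.15g %.15g %.15g %.15g %d",
                          field$params$lambda, field$params$delta,
                          field$params$beta, field$params$c0,
                          as.integer(field$params$isotropic)))
  writeLines(hdr, path)
  utils::write.table(field$values, path, append = TRUE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln[1L]), " ")[[1L]])
  }
  origin <- get("origin"); spacing <- get("spacing")
  shape <- get("shape"); prior <- get("prior")
  if (is.null(origin) || is.null(spacing) || is.null(shape))
    stop("missing grid header in ", path)
  vals <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(vals) <- NULL
  p <- get("params")
  params <- if (!is.null(p))
    plume_params(lambda = p[1L], delta = p[2L], beta = p[3L], c0 = p[4L],
                 isotropic = p[5L] == 1)
  likelihood_field(x = origin[1L] + spacing[1L] * (seq_len(shape[1L]) - 1L),
                   y = origin[2L] + spacing[2L] * (seq_len(shape[2L]) - 1L),
                   values = vals, prior = prior, params = params)
}

#' Write / read plume parameters as a key-value config
#'
#' @param params A [plume_params()].
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` a
#'   `plume_params`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "plume_params"))
  writeLines(c(sprintf("lambda = %.15g", params$lambda),
               sprintf("delta = %.15g", params$delta),
               sprintf("beta = %.15g", params$beta),
               sprintf("c0 = %.15g", params$c0),
               sprintf("isotropic = %s", tolower(params$isotropic))),
             path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  val <- function(k) kv$value[match(k, kv$key)]
  plume_params(lambda = as.numeric(val("lambda")),
               delta = as.numeric(val("delta")),
               beta = as.numeric(val("beta")),
               c0 = as.numeric(val("c0")),
               isotropic = tolower(val("isotropic")) == "true")
}

#' Write / read realization records as tab-delimited text
#'
#' One row per inference realization (truth, estimate, mechanism, noise
#' level, detection fraction, counts, seed, exclusion flag).
#'
#' @param records A record data frame (see [run_scenario()]).
#' @param path File path.
#' @return `write_records` returns `path` invisibly; `read_records` the
#'   data frame.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
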