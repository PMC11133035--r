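# File interchange: delimited-text stimulus/response tables, template
# images as text or PNG, reconstruction dumps with a JSON sidecar.

#' Read and write stimulus-response tables as delimited text
#'
#' The interchange format for externally collected yes/no data: one row
#' per trial, the first `m` columns the stimulus pixels in row-major
#' order, the last column the response. Responses are written in the
#' \{1, 0\} yes/no coding and mapped to the internal \{-1, +1\} coding on
#' load; files already coded \{-1, +1\} are accepted as-is.
#'
#' @param stimuli an `rc_stimuli`.
#' @param responses an `rc_responses` of matching length.
#' @param file path to a delimited text file.
#' @param sep field separator (default tab).
#' @return `write_stimulus_response()` returns `file` invisibly;
#'   `read_stimulus_response()` returns a list with components `stimuli`
#'   and `responses`.
#' @export
write_stimulus_response <- function(stimuli, responses, file, sep = "\t") {
  check_pair(stimuli, responses)
  y01 <- as.integer(responses$values > 0)
  utils::write.table(cbind(stimuli$matrix, y01), file, sep = sep,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @param shape stimulus shape `(height, width)`; `height * width` must
#'   equal the number of stimulus columns.
#' @rdname write_stimulus_response
#' @export
read_stimulus_response <- function(file, shape, sep = "\t") {
  shape <- check_shape(shape)
  tab <- as.matrix(utils::read.table(file, sep = sep, header = FALSE))
  m <- shape[1] * shape[2]
  if (ncol(tab) != m + 1) {
    stop("file has ", ncol(tab), " columns; expected ", m,
         " pixels + 1 response", call. = FALSE)
  }
  list(stimuli = stimulus_set(tab[, seq_len(m), drop = FALSE], shape),
       responses = response_vector(tab[, m + 1]))
}

#' Export a template as delimited text or PNG
#'
#' @param template an [new_template()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_template_text <- function(template, file) {
  stopifnot(inherits(template, "rc_template"))
  utils::write.table(round(template$pixels, 6), file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_template_text
#' @export
write_template_png <- function(template, file) {
  stopifnot(inherits(template, "rc_template"))
  png::writePNG(template$pixels, file)
  invisible(file)
}

#' Read a template from delimited text
#'
#' @param file a comma-separated matrix of intensities in \[0, 1\].
#' @param label label for the loaded template.
#' @return an [new_template()].
#' @export
read_template_text <- function(file, label = "") {
  px <- as.matrix(utils::read.csv(file, header = FALSE))
  dimnames(px) <- NULL
  new_template(px, label = label)
}

#' Write a reconstruction with metadata sidecar
#'
#' Dumps the raw pixel estimate losslessly as delimited text
#' (`<prefix>.txt`), a min-max scaled PNG for display
#' (`<prefix>.png`), and a JSON metadata sidecar (`<prefix>.json`)
#' recording method, trials used, sparsity, and provenance. For
#' compressive-sensing fits, pass the `coefficients` element to also dump
#' the sparse basis coefficients (`<prefix>_coef.txt`).
#'
#' @param rec an `rc_reconstruction`.
#' @param prefix output path prefix (directory must exist).
#' @param coefficients optional `rc_sparse_coef` to dump alongside.
#' @return the sidecar path, invisibly.
#' @export
write_reconstruction <- function(rec, prefix, coefficients = NULL) {
  stopifnot(inherits(rec, "rc_reconstruction"))
  img <- reconstruction_image(rec)
  utils::write.table(img, paste0(prefix, ".txt"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  png::writePNG(scaled, paste0(prefix, ".png"))
  meta <- list(method = rec$method, n_used = rec$n_used,
               shape = rec$shape, gamma = rec$gamma,
               provenance = rec$provenance)
  if (!is.null(coefficients)) {
    stopifnot(inherits(coefficients, "rc_sparse_coef"))
    utils::write.table(coefficients$s_hat, paste0(prefix, "_coef.txt"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    meta$lambda_used <- coefficients$lambda_used
    meta$basis <- list(height = coefficients$basis$height,
                       width = coefficients$basis$width,
                       family = coefficients$basis$family)
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(sidecar)
}

#' Serialize a quality report or gamma search to JSON
#'
#' @param x an `rc_quality` or `rc_gamma_search` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report_json <- function(x, file) {
  jsonlite::write_json(unclass(strip_nonserializable(x)), file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(file)
}

strip_nonserializable <- function(x) {
  lapply(x, function(el) {
    if (inherits(el, "rc_noise") || inherits(el, "basis_spec")) {
      unclass(el)
    } else if (is.matrix(el)) {
      apply(el, 1, identity, simplify = FALSE)
    } else {
      el
    }
  })
}

#' Append grid results to a run-level CSV
#'
#' One row per method x condition x replicate; creates the file with a
#' header if absent, appends without one otherwise.
#'
#' @param results the `data.frame` from [run_grid()].
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
append_results_csv <- function(results, file) {
  new <- !file.exists(file)
  utils::write.table(results, file, sep = ",", row.names = FALSE,
                     col.names = new, append = !new)
  invisible(file)
}
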