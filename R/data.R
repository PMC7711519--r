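# Bundled example datasets and the synthetic-data generator.

.dataset_info <- list(
  fiber_20mm = list(n = 69L,  units = "GPa",
                    what = "tensile strength of single carbon fibres, 20 mm gauge length"),
  fiber_10mm = list(n = 63L,  units = "GPa",
                    what = "tensile strength of single carbon fibres, 10 mm gauge length"),
  bank_A     = list(n = 100L, units = "minutes",
                    what = "customer waiting times before service, bank A"),
  bank_B     = list(n = 60L,  units = "minutes",
                    what = "customer waiting times before service, bank B"))

#' Load a bundled dataset
#'
#' Four classic stress-strength benchmark samples ship with the package:
#' the 20 mm and 10 mm gauge-length single carbon-fibre tensile strengths
#' (`fiber_20mm`, n = 69; `fiber_10mm`, n = 63) and the waiting times before
#' service at two bank counters (`bank_A`, n = 100; `bank_B`, n = 60).  In
#' the worked examples the longer-gauge fibres / bank A play the strength
#' role and the other sample the stress role.
#'
#' @param name one of `"fiber_20mm"`, `"fiber_10mm"`, `"bank_A"`, `"bank_B"`.
#' @return An object of class `"named_dataset"`: list with `name`, `values`,
#'   `n`, `units`.
#' @examples
#' load_dataset("fiber_20mm")
#' @export
load_dataset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.dataset_info)) {
    stop("unknown dataset; choices are: ",
         paste(names(.dataset_info), collapse = ", "), call. = FALSE)
  }
  info <- .dataset_info[[name]]
  path <- system.file("extdata", paste0(name, ".txt"), package = "phldss",
                      mustWork = TRUE)
  values <- read_sample(path)
  if (length(values) != info$n || any(values <= 0)) {
    stop(sprintf("dataset '%s' failed validation (expected %d positive values)",
                 name, info$n), call. = FALSE)
  }
  structure(list(name = name, values = values, n = info$n, units = info$units),
            class = "named_dataset")
}

#' @export
print.named_dataset <- function(x, ...) {
  cat(sprintf("%s: n = %d values in %s (range %.3f - %.3f)\n",
              x$name, x$n, x$units, min(x$values), max(x$values)))
  invisible(x)
}

#' Export a bundled dataset to the one-value-per-line text format
#'
#' @param dataset a [load_dataset()] result.
#' @param path output file path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "named_dataset"))
  writeLines(format(dataset$values, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Generate synthetic stress-strength samples
#'
#' Inverse-transform samples from the two PHLD marginals of `spec`,
#' reproducible per seed (the two marginals use sub-seeds derived from
#' `seed`, so the strength sample does not change when only `n2` does).
#'
#' @param spec an [ss_spec()].
#' @param n1,n2 sample sizes.
#' @param seed optional integer seed.
#' @return An [ss_data()] object.
#' @examples
#' generate_synthetic(ss_spec(2, 1.9, 3.7, 3.8), 20, 20, seed = 1)
#' @export
generate_synthetic <- function(spec, n1, n2, seed = NULL) {
  stopifnot(inherits(spec, "ss_spec"), n1 >= 1, n2 >= 1)
  sx <- if (is.null(seed)) NULL else .derive_seed(seed, 1L)
  sy <- if (is.null(seed)) NULL else .derive_seed(seed, 2L)
  ss_data(rphld(n1, spec$alpha1, spec$lambda1, seed = sx),
          rphld(n2, spec$alpha2, spec$lambda2, seed = sy))
}
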