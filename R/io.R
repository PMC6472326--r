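# Plain-text interchange: CSV tables with labelled headers and index
# column, plus JSON manifests.

#' Write a SAM to CSV
#'
#' @param sam square matrix with account dimnames.
#' @param path output file.
#' @export
write_sam_csv <- function(sam, path) {
  utils::write.csv(as.data.frame(sam), path, row.names = TRUE)
}

#' Read a SAM from CSV
#'
#' @param path CSV file written by [write_sam_csv()].
#' @return square numeric matrix with account dimnames.
#' @export
read_sam_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write AIDS parameters to JSON with a constraint-residual report
#'
#' @param params an `aids_parameters` object.
#' @param path output file.
#' @export
write_aids_json <- function(params, path) {
  jsonlite::write_json(list(
    alpha = as.list(params$alpha),
    beta = as.list(params$beta),
    gamma = params$gamma,
    alpha0 = params$alpha0,
    shares0 = as.list(params$shares0),
    constraint_residuals = as.list(aids_constraint_residuals(params))
  ), path, auto_unbox = TRUE, digits = NA)
}

#' Read AIDS parameters from JSON
#'
#' @param path file written by [write_aids_json()].
#' @return an `aids_parameters` object.
#' @export
read_aids_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as.matrix(x$gamma)
  lbl <- names(x$alpha)
  dimnames(g) <- list(lbl, lbl)
  structure(list(alpha = unlist(x$alpha), gamma = g, beta = unlist(x$beta),
                 alpha0 = x$alpha0, shares0 = unlist(x$shares0)),
            class = "aids_parameters")
}

#' Write a synthetic dataset to a directory of CSV tables
#'
#' One CSV per calibration table plus a JSON manifest recording the
#' dimensions, seed and noise level of the generator call.
#'
#' @param gen result of [generate_synthetic_economy()].
#' @param dir output directory.
#' @param seed,noise_level provenance recorded in the manifest.
#' @return invisibly, the directory.
#' @export
write_synthetic_dataset <- function(gen, dir, seed = NA,
                                    noise_level = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- gen$truth
  dims <- truth$dims
  write_sam_csv(truth$balanced_sam, file.path(dir, "sam_balanced.csv"))
  write_sam_csv(gen$unbalanced_sam, file.path(dir, "sam_prior.csv"))
  nc <- truth$nutrient_coefficients
  utils::write.csv(as.data.frame(nc$energy_density),
                   file.path(dir, "energy_density.csv"))
  for (f in c("sfa", "mufa", "pufa")) {
    utils::write.csv(as.data.frame(nc[[f]]),
                     file.path(dir, paste0("fraction_", f, ".csv")))
  }
  utils::write.csv(as.data.frame.table(truth$population$counts,
                                       responseName = "count"),
                   file.path(dir, "population.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(truth$luc_matrix)),
                   file.path(dir, "luc_matrix.csv"))
  for (h in dims$households) {
    write_aids_json(truth$aids_parameters[[h]],
                    file.path(dir, paste0("aids_", h, ".json")))
    ep <- gen$elasticity_priors[[h]]
    utils::write.csv(as.data.frame(ep$eps),
                     file.path(dir, paste0("elasticity_prior_", h, ".csv")))
  }
  jsonlite::write_json(list(
    commodities = dims$commodities, households = dims$households,
    periods = dims$periods, strata_count = dims$strata_count,
    seed = seed, noise_level = noise_level
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
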