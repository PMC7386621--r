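# Plain-text serialization: twin datasets as CSV with a JSON sidecar,
# mesh plans / solutions / configurations as JSON.

#' Write a twin dataset to CSV with a JSON provenance sidecar
#'
#' Columns time_ms, I_inj_pA, V_use_mV, V_exp_mV; the sidecar
#' (<path>.json) holds sigma, zeta, dt, protocol steps and the physical
#' constants so the dataset round-trips losslessly.
#'
#' @param dataset a twin dataset
#' @param path CSV path
#' @export
write_twin_csv <- function(dataset, path) {
  df <- data.frame(time_ms = dataset$t, I_inj_pA = dataset$I_inj,
                   V_use_mV = dataset$V_use, V_exp_mV = dataset$V_exp)
  write.csv(df, path, row.names = FALSE)
  meta <- list(sigma = dataset$sigma, zeta = dataset$zeta,
               dt_base = dataset$dt_base,
               protocol = list(name = dataset$protocol$name,
                               steps = dataset$protocol$steps),
               consts = as.list(dataset$consts),
               p_true = if (!is.null(dataset$p_true))
                 as.list(dataset$p_true) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a twin dataset written by [write_twin_csv()]
#' @param path CSV path (sidecar <path>.json must exist)
#' @export
read_twin_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  steps <- as.data.frame(meta$protocol$steps)
  protocol <- build_step_protocol(steps)
  protocol$name <- meta$protocol$name
  structure(list(
    t = df$time_ms, I_inj = df$I_inj_pA, V_use = df$V_use_mV,
    V_exp = df$V_exp_mV, sigma = meta$sigma, zeta = meta$zeta,
    dt_base = meta$dt_base, protocol = protocol,
    p_true = if (!is.null(meta$p_true)) unlist(meta$p_true) else NULL,
    consts = unlist(meta$consts)), class = "twin_dataset")
}

#' Write a solution record to JSON (+ optional trajectory CSV)
#' @param sol a [solve_nlp()] record
#' @param path JSON path
#' @param trajectory_csv optional CSV path for the state/control
#'   trajectory
#' @export
write_solution_json <- function(sol, path, trajectory_csv = NULL) {
  out <- list(p_est = as.list(sol$p_est), cost = sol$cost,
              feasibility = sol$feasibility,
              kkt_optimality = sol$kkt_optimality, status = sol$status,
              iterations = sol$iterations, sigma = sol$sigma,
              zeta = sol$zeta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(trajectory_csv)) {
    df <- as.data.frame(sol$states)
    df$u <- sol$u
    write.csv(df, trajectory_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Write a mesh plan to JSON
#' @param mesh a mesh plan
#' @param path JSON path
#' @export
write_mesh_json <- function(mesh, path) {
  jsonlite::write_json(
    list(index = mesh$index, grp_start = mesh$grp_start,
         grp_dt = mesh$grp_dt, threshold = mesh$threshold, m = mesh$m,
         dt_base = mesh$dt_base, n_retained = mesh$n_retained),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Round-trip a model/parameter configuration through JSON
#'
#' Serializes parameter values, bounds and physical constants at full
#' double precision (17 significant digits).
#'
#' @param params named parameter vector
#' @param bounds list(lower, upper)
#' @param consts physical constants
#' @param path JSON path
#' @export
write_config_json <- function(params, bounds = rvlm_bounds(),
                              consts = physical_constants(), path) {
  jsonlite::write_json(
    list(params = as.list(params),
         bounds = list(lower = as.list(bounds$lower),
                       upper = as.list(bounds$upper)),
         consts = as.list(consts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  cf <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = unlist(cf$params),
       bounds = list(lower = unlist(cf$bounds$lower),
                     upper = unlist(cf$bounds$upper)),
       consts = unlist(cf$consts))
}
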