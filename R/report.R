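#' Read a plain key = value run configuration
#'
#' One \code{key = value} pair per line; blank lines and lines starting
#' with \code{#} are ignored.  Values are parsed as numeric or logical
#' where possible, otherwise kept as strings.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}

default_run_config <- function() {
  list(system = "schnakenberg", D_u = 1/1000, D_v = 1/10, L = 0.2,
       bc = "dirichlet",
       stages = "linear,amplitude",
       truncation_N = 128, n_nodes = 256, n_interior = 200,
       t_end = 100, sigma = 0.01, seed = 1,
       L_range_min = 0.04, L_range_max = 1.0,
       out_dir = ".")
}

#' Run the analysis chain and write a report
#'
#' Executes the requested stages in dependency order -- steady state and
#' linear analysis, amplitude equations, patterning region, simulation,
#' continuation -- and writes a JSON summary plus CSV tables to the output
#' directory.  Outputs are deterministic given the configuration (the seed
#' covers the only random ingredient, random initial conditions).
#'
#' @param config named list (see \code{\link{read_run_config}}; missing
#'   entries take defaults) or a path to a key = value file.
#' @param out_dir output directory (overrides \code{config$out_dir}).
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) the report list written to \code{report.json}.
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' rep <- run_report(list(stages = "linear,amplitude"), out_dir = dir)
#' round(rep$amplitude$dirichlet$p1, 2)
#' }
#' @export
run_report <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- trimws(strsplit(as.character(cfg$stages), ",")[[1]])
  log_stage <- function(stage, ...) {
    if (!quiet)
      message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                      stage, paste0(..., collapse = " ")))
  }
  set.seed(as.integer(cfg$seed))
  sys <- if (identical(cfg$system, "schnakenberg"))
    schnakenberg(D_u = cfg$D_u, D_v = cfg$D_v, L = cfg$L)
  else rd_system(cfg$f, cfg$g, cfg$D_u, cfg$D_v, cfg$L)
  report <- list(config = cfg)
  errors <- list()

  la <- tryCatch(linear_analysis(sys), error = function(e) e)
  if (inherits(la, "error")) {
    errors$linear <- conditionMessage(la)
    report$errors <- errors
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(report))
  }
  if ("linear" %in% stages) {
    report$linear <- list(
      ode_stable = la$ode_stable, diffusion_driven = la$diffusion_driven,
      L_c = la$L_c,
      k_minus = sqrt(la$k_minus_sq) * la$L_c / sys$L,  # window at L = L_c
      k_plus = sqrt(la$k_plus_sq) * la$L_c / sys$L,
      Lambda = la$Lambda, eta = la$eta)
    log_stage("linear", sprintf("L_c = %.6g", la$L_c))
  }
  if (!la$diffusion_driven) {
    errors$linear <- "no diffusion-driven instability; downstream stages skipped"
    log_stage("linear", errors$linear)
    report$errors <- errors
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(report))
  }

  if ("amplitude" %in% stages) {
    amp <- amplitude_equations(sys, truncation_N = cfg$truncation_N)
    report$amplitude <- list(
      L_c = la$L_c,
      dirichlet = amp$dirichlet[c("p1", "p2", "p3", "p4", "p5", "slope_m")],
      neumann = amp$neumann[c("lin", "cub")])
    Lgrid <- seq(la$L_c * 0.97, la$L_c * 1.05, length.out = 41)
    pb <- rbind(
      predicted_branch(amp$dirichlet, la$steady_state, la$kernel_vector,
                       Lgrid, la$L_c, "quadratic"),
      predicted_branch(amp$dirichlet, la$steady_state, la$kernel_vector,
                       Lgrid, la$L_c, "cubic"),
      predicted_branch(amp$neumann, la$steady_state, la$kernel_vector,
                       Lgrid, la$L_c))
    utils::write.csv(pb, file.path(out_dir, "predicted_branches.csv"),
                     row.names = FALSE)
    log_stage("amplitude",
              sprintf("p1 = %.2f, p2 = %.2f, neumann cub = %.2f",
                      amp$dirichlet$p1, amp$dirichlet$p2, amp$neumann$cub))
  }

  if ("region" %in% stages) {
    reg <- patterning_region(sys, la$derivs)
    utils::write.csv(reg$boundary, file.path(out_dir, "region_boundary.csv"),
                     row.names = FALSE)
    report$region <- list(L_min = reg$extremes$L_min,
                          D_v_min = reg$extremes$D_v_min,
                          L_at_D_v_min = reg$extremes$L_at_D_v_min)
    log_stage("region", sprintf("L_min = %.4f, D_v_min = %.4f",
                                reg$extremes$L_min, reg$extremes$D_v_min))
  }

  if ("simulate" %in% stages) {
    tr <- simulate_rd(sys, cfg$bc, t_end = cfg$t_end, n_nodes = cfg$n_nodes,
                      L = cfg$L, ic = "random", sigma = cfg$sigma,
                      seed = as.integer(cfg$seed),
                      kernel_u = la$kernel_vector[1])
    utils::write.csv(
      data.frame(t = tr$times, L = tr$L_of_t, max_u = tr$max_u,
                 min_u = tr$min_u, a = tr$a),
      file.path(out_dir, "trace.csv"), row.names = FALSE)
    report$simulate <- list(final_max_u = tr$max_u[length(tr$times)],
                            final_min_u = tr$min_u[length(tr$times)],
                            final_a = tr$a[length(tr$times)])
    log_stage("simulate", sprintf("final max(u) = %.4g", report$simulate$final_max_u))
  }

  if ("continue" %in% stages) {
    disc <- discretize_steady(sys, cfg$bc, n_interior = cfg$n_interior)
    hom <- corrector(disc, max(cfg$L_range_min, la$L_c * 0.9),
                     disc$homogeneous())
    br <- continue_branch(disc, hom, +1,
                          L_window = c(cfg$L_range_min, cfg$L_range_max))
    br <- detect_events(br, disc)
    utils::write.csv(branch_diagram(br), file.path(out_dir, "branch.csv"),
                     row.names = FALSE)
    report$continuation <- list(
      n_points = length(br$points),
      events = br$events)
    log_stage("continue", sprintf("%d points, %d events",
                                  length(br$points), nrow(br$events)))
  }

  if (length(errors)) report$errors <- errors
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
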