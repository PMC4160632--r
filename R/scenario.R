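# Config-driven scenario runner: baseline plus parameter-override variants
# (lining modulus x100 / /100 on its real or imaginary part, lining density
# low / x10 / heavy-head), each producing impedance and probe-acceleration
# CSVs, an extrema report, optional VTK displacement fields, and a YAML
# manifest that fully reproduces the run. Everything is deterministic:
# identical configs give byte-identical CSV numbers.

#' Build a scenario description
#'
#' A scenario bundles everything one simulation campaign needs: geometry
#' (a [shell_spec()]-style list, or a path to an MSH mesh), materials by
#' region, the drive, the frequency grid, response probes, field-export
#' requests and a list of parameter-override variants. Scenarios are plain
#' lists that round-trip through YAML ([read_scenario()], [write_scenario()]).
#'
#' @param name scenario name.
#' @param geometry list; either `list(kind = "shell", ...)` with
#'   [shell_spec()] arguments plus `calibrate = TRUE` to calibrate layer
#'   thicknesses to the target masses, or `list(kind = "mesh", path = ...)`.
#' @param materials named list of material descriptions
#'   (`list(E1=, nu=, rho=, loss=list(kind=, ...))`) or a [material_set()].
#' @param load list: `node_set` (or `position`/`node`), `direction`,
#'   `amplitude` in N.
#' @param grid list: `n`, `f_min`, `f_max` (log-spaced), or `frequencies`.
#' @param probes named list mapping probe labels to node-set names.
#' @param fields list: `frequencies` (Hz), `phases_deg`, `variants`
#'   (logical: export fields for variants too, default FALSE). `NULL`
#'   disables field export.
#' @param variants list of overrides: each
#'   `list(name=, region=, scale=list(E1=, eta=, rho=), set=list(rho=, ...))`.
#' @return a `scenario` object.
#' @export
scenario <- function(name = "scenario",
                     geometry = list(kind = "shell", calibrate = TRUE),
                     materials = material_preset(),
                     load = list(node_set = "stim_site",
                                 direction = c(1, 0, 0), amplitude = 1e-6),
                     grid = list(n = 60, f_min = 100, f_max = 10000),
                     probes = list(ipsi = "ipsi_cochlea",
                                   contra = "contra_cochlea"),
                     fields = list(frequencies = c(100, 600),
                                   phases_deg = c(0, 180),
                                   variants = FALSE),
                     variants = list()) {
  if (inherits(materials, "material_set"))
    materials <- lapply(materials, material_to_config)
  sc <- structure(
    list(name = name, geometry = geometry, materials = materials,
         load = load, grid = grid, probes = probes, fields = fields,
         variants = variants),
    class = "scenario")
  validate_scenario(sc)
  sc
}

material_to_config <- function(m) {
  loss <- if (m$loss$kind == "constant")
    list(kind = "constant", eta0 = m$loss$eta0)
  else list(kind = "linear_in_f", alpha_f = m$loss$alpha_f)
  list(E1 = m$E1, nu = m$nu, rho = m$rho, loss = loss)
}

material_from_config <- function(cfg) {
  loss <- cfg$loss
  lm <- if (is.null(loss)) loss_constant(0)
  else switch(loss$kind,
              constant = loss_constant(loss$eta0),
              linear_in_f =
                if (!is.null(loss$alpha_f)) loss_linear(alpha_f = loss$alpha_f)
                else loss_linear(eta_ref = loss$eta_ref, f_ref = loss$f_ref),
              stop("unknown loss kind '", loss$kind, "'"))
  material(cfg$E1, cfg$nu, cfg$rho, lm)
}

scenario_material_set <- function(sc) {
  material_set(lapply(sc$materials, material_from_config))
}

validate_scenario <- function(sc) {
  geom_regions <- if (identical(sc$geometry$kind, "shell"))
    c("bone", "polyurethane") else NULL
  if (!is.null(geom_regions)) {
    bad <- setdiff(geom_regions, names(sc$materials))
    if (length(bad))
      stop("scenario validation: no material for region(s) ",
           paste(bad, collapse = ", "))
  }
  for (v in sc$variants) {
    if (is.null(v$name)) stop("scenario validation: variant without a name")
    if (!is.null(v$region) && !v$region %in% names(sc$materials))
      stop("scenario validation: variant '", v$name,
           "' overrides unknown region '", v$region, "'")
    pars <- c(names(v$scale), names(v$set))
    bad <- setdiff(pars, c("E1", "eta", "eta0", "rho", "nu"))
    if (length(bad))
      stop("scenario validation: variant '", v$name,
           "' overrides unknown parameter(s) ", paste(bad, collapse = ", "))
  }
  invisible(sc)
}

#' The shipped dry-skull scenario preset
#'
#' Baseline: the mass-calibrated two-layer surrogate (bone 470 g,
#' polyurethane lining 340 g) driven at the stimulation site along the
#' medial (x) axis, 60 log-spaced frequencies over 0.1-10 kHz. Seven
#' variants scale the lining properties: its storage modulus x100 and
#' /100, its loss factor x100 and /100, and its density to 99.740 kg/m^3
#' (34 g lining), x10 (the 1/sqrt(mass) resonance check) and 8800 kg/m^3
#' (the heavy-head case: about 3 kg lining, 3.47 kg total).
#'
#' @param name preset name (only `"stenfelt2002_dry_skull"`).
#' @param refinement_level,grid_n optional size overrides for the surrogate
#'   mesh and frequency grid.
#' @return a [scenario()].
#' @export
scenario_preset <- function(name = "stenfelt2002_dry_skull",
                            refinement_level = 3, grid_n = 60) {
  if (!identical(name, "stenfelt2002_dry_skull"))
    stop("unknown preset '", name, "'")
  scenario(
    name = name,
    geometry = list(kind = "shell", outer_radius = 0.08,
                    refinement_level = refinement_level,
                    layers_bone = 3, layers_lining = 2,
                    target_bone_mass = 0.470, target_lining_mass = 0.340,
                    calibrate = TRUE),
    materials = material_preset(name),
    grid = list(n = grid_n, f_min = 100, f_max = 10000),
    variants = list(
      # constant complex lining moduli: {1e8+1e4i}, {1e4+1e4i}, {1e6+1e6i},
      # {1e6+1e2i} -- the normal lining is {1e6 + 1e4i} at 100 Hz
      list(name = "re_x100", region = "polyurethane",
           set = list(E1 = 1e8, eta0 = 1e-4)),
      list(name = "re_d100", region = "polyurethane",
           set = list(E1 = 1e4, eta0 = 1)),
      list(name = "im_x100", region = "polyurethane", set = list(eta0 = 1)),
      list(name = "im_d100", region = "polyurethane", set = list(eta0 = 1e-4)),
      list(name = "rho_low", region = "polyurethane", set = list(rho = 99.740)),
      list(name = "rho_x10", region = "polyurethane", scale = list(rho = 10)),
      list(name = "heavy_head", region = "polyurethane",
           set = list(rho = 8800))))
}

#' Apply a variant override to a material set
#'
#' @param materials a [material_set()].
#' @param variant a variant description (see [scenario()]).
#' @return the modified `material_set`.
#' @export
apply_variant <- function(materials, variant) {
  materials <- material_set(materials)
  r <- variant$region
  if (!r %in% names(materials))
    stop("variant '", variant$name, "': unknown region '", r, "'")
  m <- materials[[r]]
  E1 <- m$E1; nu <- m$nu; rho <- m$rho; loss <- m$loss
  sc <- variant$scale
  if (!is.null(sc$E1)) E1 <- E1 * sc$E1
  if (!is.null(sc$rho)) rho <- rho * sc$rho
  if (!is.null(sc$eta))
    loss <- if (loss$kind == "constant") loss_constant(loss$eta0 * sc$eta)
            else loss_linear(alpha_f = loss$alpha_f * sc$eta)
  st <- variant$set
  if (!is.null(st$E1)) E1 <- st$E1
  if (!is.null(st$rho)) rho <- st$rho
  if (!is.null(st$nu)) nu <- st$nu
  if (!is.null(st$eta0)) loss <- loss_constant(st$eta0)
  materials[[r]] <- material(E1, nu, rho, loss)
  materials
}

#' Derive the heavy-head variant of a calibrated scenario
#'
#' Sets the lining density to 8800 kg/m^3 at unchanged geometry, turning
#' the 340 g lining into about 3 kg so that skull plus lining approximate
#' the mass of an intact human head (about 3.47 kg in total). Requires a
#' mass-calibrated shell baseline.
#'
#' @param sc a [scenario()] with a calibrated shell geometry.
#' @return a `scenario` whose lining density is 8800 kg/m^3.
#' @export
heavy_head_variant <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (!identical(sc$geometry$kind, "shell") ||
      !isTRUE(sc$geometry$calibrate))
    stop("heavy-head variant requires a mass-calibrated shell baseline")
  sc$name <- paste0(sc$name, "_heavy_head")
  sc$materials$polyurethane$rho <- 8800
  sc$variants <- list()
  validate_scenario(sc)
  sc
}

#' Read / write scenario YAML configs
#'
#' @param path a YAML file.
#' @return `read_scenario()`: a [scenario()]; `write_scenario()`: `path`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$load$direction <- as.numeric(cfg$load$direction)
  do.call(scenario, cfg)
}

#' @rdname read_scenario
#' @param sc a [scenario()].
#' @export
write_scenario <- function(sc, path) {
  yaml::write_yaml(unclass(sc), path)
  invisible(path)
}

scenario_mesh <- function(sc) {
  g <- sc$geometry
  if (identical(g$kind, "mesh")) return(list(mesh = read_msh(g$path),
                                             spec = NULL))
  args <- g[setdiff(names(g), c("kind", "calibrate"))]
  spec <- do.call(shell_spec, args)
  if (isTRUE(g$calibrate)) {
    rho <- vapply(sc$materials, function(m) m$rho, numeric(1))
    spec <- calibrate_masses(spec, rho[c("bone", "polyurethane")])
  }
  list(mesh = generate_shell(spec), spec = spec)
}

#' Run a scenario campaign
#'
#' Executes the baseline and every variant: assembly, frequency sweep,
#' impedance and probe-acceleration CSVs, an extrema report, optional VTK
#' displacement-field exports, and a YAML manifest of all resolved
#' parameters. A failing variant is recorded and the remaining variants
#' proceed; the returned summary then carries `attr(, "status") == 2`
#' instead of 0.
#'
#' @param config a [scenario()] or the path of a YAML config.
#' @param outdir output directory (created; one subdirectory per run).
#' @param quiet suppress progress messages.
#' @return tibble summarising the runs (name, status, resonance frequency
#'   and level, total mass, output directory), with attribute `status`.
#' @export
run_scenario <- function(config, outdir = tempfile("vibroskull_"),
                         quiet = FALSE) {
  sc <- if (is.character(config)) read_scenario(config) else config
  stopifnot(inherits(sc, "scenario"))
  validate_scenario(sc)
  say <- function(...) if (!quiet) message(...)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- scenario_mesh(sc)
  mesh <- gm$mesh
  say("mesh: ", n_nodes(mesh), " nodes, ", n_elements(mesh), " elements")

  base_mats <- scenario_material_set(sc)
  grid <- do.call(frequency_grid, sc$grid)
  load_args <- sc$load
  load_args$direction <- as.numeric(load_args$direction)
  load <- do.call(point_load, c(list(mesh = mesh), load_args))

  runs <- c(list(list(name = "baseline")), sc$variants)
  rows <- list()
  status <- 0L
  for (run in runs) {
    rname <- run$name
    rdir <- file.path(outdir, rname)
    dir.create(rdir, showWarnings = FALSE)
    row <- tryCatch({
      mats <- if (identical(rname, "baseline")) base_mats
              else apply_variant(base_mats, run)
      sys <- assemble_system(mesh, mats)
      say(rname, ": assembled ", sys$n_dof, " dofs, total mass ",
          format(total_mass(sys), digits = 4), " kg")
      sol <- solve_sweep(sys, load, grid)
      say(rname, ": swept ", length(grid), " frequencies, max residual ",
          format(max(sol$residuals), digits = 3))
      imp <- point_impedance(sol)
      write_spectrum_csv(imp, file.path(rdir, "impedance.csv"))
      acc <- list()
      for (p in names(sc$probes)) {
        acc[[p]] <- probe_acceleration(sol, sc$probes[[p]])
        write_spectrum_csv(acc[[p]],
                           file.path(rdir, paste0("accel_", p, ".csv")))
      }
      write_extrema_report(imp, acc, file.path(rdir, "extrema.txt"))
      if (!is.null(sc$fields) &&
          (identical(rname, "baseline") || isTRUE(sc$fields$variants)))
        export_fields(sys, load, mesh, sc$fields, rdir)
      ex <- find_extrema(imp)
      res <- ex[ex$type == "resonance", , drop = FALSE]
      manifest <- list(
        scenario = sc$name, run = rname,
        package_version = as.character(utils::packageVersion("vibroskull")),
        geometry = if (!is.null(gm$spec)) unclass(gm$spec) else sc$geometry,
        materials = lapply(mats, material_to_config),
        load = sc$load, grid = list(frequencies = grid),
        probes = sc$probes,
        total_mass_kg = total_mass(sys),
        region_mass_kg = as.list(vapply(names(sys$M_regions), function(r)
          total_mass(sys, r), numeric(1))),
        max_residual = max(sol$residuals),
        f_resonance_hz = if (nrow(res)) res$f_hz[1L] else NA)
      yaml::write_yaml(manifest, file.path(rdir, "manifest.yaml"))
      tibble::tibble(
        run = rname, status = "ok",
        f_res_hz = if (nrow(res)) res$f_hz[1L] else NA_real_,
        level_db = if (nrow(res)) res$level_db[1L] else NA_real_,
        total_mass_kg = total_mass(sys), dir = rdir)
    }, error = function(e) {
      status <<- 2L
      say(rname, ": FAILED (", conditionMessage(e), ")")
      writeLines(conditionMessage(e), file.path(rdir, "error.txt"))
      tibble::tibble(run = rname, status = "error", f_res_hz = NA_real_,
                     level_db = NA_real_, total_mass_kg = NA_real_,
                     dir = rdir)
    })
    rows[[rname]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "status") <- status
  attr(out, "outdir") <- outdir
  out
}

write_extrema_report <- function(imp, acc, path) {
  lines <- c("# impedance extrema (resonance = |Zm| minimum)")
  ex <- find_extrema(imp)
  lines <- c(lines, if (nrow(ex))
    sprintf("%-14s f = %10.3f Hz  level = %8.3f dB", ex$type, ex$f_hz,
            ex$level_db) else "  (monotone trace)")
  for (p in names(acc)) {
    lines <- c(lines, paste0("# ", p, " acceleration extrema"))
    ex <- find_extrema(acc[[p]])
    lines <- c(lines, if (nrow(ex))
      sprintf("%-14s axis %s  f = %10.3f Hz  level = %8.3f dB",
              ex$type, ex$axis, ex$f_hz, ex$level_db) else "  (monotone)")
  }
  writeLines(lines, path)
  invisible(path)
}

export_fields <- function(sys, load, mesh, fields, rdir) {
  freqs <- fields$frequencies %||% c(100, 600)
  phases <- fields$phases_deg %||% c(0, 180)
  sol <- solve_sweep(sys, load, sort(unique(as.numeric(freqs))))
  for (k in seq_along(sol$frequencies)) {
    x <- matrix(sol$X[, k], ncol = 3L, byrow = TRUE)
    for (ph in phases) {
      u <- Re(x * exp(1i * ph * pi / 180))
      write_fields_vtk(
        mesh, list(displacement_m = u),
        file.path(rdir, sprintf("fields_f%g_ph%03d.vtk",
                                sol$frequencies[k], as.integer(ph))))
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
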