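#' Load a scenario configuration file
#'
#' Scenario files are YAML documents with four blocks: `group` (`OC` or
#' `BDC`), `dosing` (dose, infusion duration, hepatic blood flow, liver
#' volume, and optional horizon / transit-count overrides), `parameters`
#' (one entry per model parameter: `id`, `name`, `unit`, `min`, `max`, or
#' `fixed: true` with `value`), and `objectives` (`id`, `name`, `value`).
#' The packaged `oc.yaml` and `bdc.yaml` encode the irinotecan study
#' scenarios: the OC group fixes the T-tube split ratio at zero (no
#' drainage tube), leaving 55 free parameters and 9 objectives; the BDC
#' group frees all 56 and adds the five biliary objectives (14 in total).
#'
#' Unknown keys anywhere in the document are rejected, so typos fail loudly
#' instead of silently losing a setting.
#'
#' @param path path to a scenario YAML file.
#' @return An object of class `cnm_scenario`: list with `group`, `space`
#'   ([parameter_space()]), `spec` ([objective_spec()]), `settings`
#'   ([pbpk_settings()]).
#' @examples
#' sc <- load_config(system.file("extdata", "bdc.yaml", package = "cnmpk"))
#' n_free(sc$space)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  allowed_top <- c("schema", "group", "dosing", "parameters", "objectives")
  check_keys(doc, allowed_top, "top level")
  for (req in c("group", "dosing", "parameters", "objectives"))
    if (is.null(doc[[req]])) stop("config is missing the '", req, "' block")
  if (!doc$group %in% c("OC", "BDC"))
    stop("group must be 'OC' or 'BDC'; got '", doc$group, "'")

  check_keys(doc$dosing,
             c("dose", "infusion_duration", "Q_liver", "V_liver",
               "t_end", "n_bile_transit"), "dosing block")
  settings <- do.call(pbpk_settings, c(list(group = doc$group), doc$dosing))

  par_fields <- c("id", "name", "unit", "min", "max", "fixed", "value")
  rows <- lapply(seq_along(doc$parameters), function(i) {
    e <- doc$parameters[[i]]
    check_keys(e, par_fields, paste0("parameter entry ", i))
    if (is.null(e$name)) stop("parameter entry ", i, " has no name")
    fixed <- isTRUE(e$fixed)
    if (!fixed && (is.null(e$min) || is.null(e$max)))
      stop("free parameter '", e$name, "' needs min and max")
    if (fixed && is.null(e$value))
      stop("fixed parameter '", e$name, "' needs a value")
    list(id = if (is.null(e$id)) i else e$id, name = e$name,
         unit = if (is.null(e$unit)) "" else e$unit,
         min = if (is.null(e$min)) NA_real_ else as.numeric(e$min),
         max = if (is.null(e$max)) NA_real_ else as.numeric(e$max),
         fixed = fixed,
         value = if (is.null(e$value)) NA_real_ else as.numeric(e$value))
  })
  space <- parameter_space(
    names = vapply(rows, `[[`, "", "name"),
    lower = vapply(rows, `[[`, 0, "min"),
    upper = vapply(rows, `[[`, 0, "max"),
    units = vapply(rows, `[[`, "", "unit"),
    fixed = vapply(rows, `[[`, FALSE, "fixed"),
    values = vapply(rows, `[[`, 0, "value"))

  obj_rows <- lapply(seq_along(doc$objectives), function(i) {
    e <- doc$objectives[[i]]
    check_keys(e, c("id", "name", "value", "weight"), paste0("objective entry ", i))
    if (is.null(e$name) || is.null(e$value))
      stop("objective entry ", i, " needs name and value")
    list(name = e$name, value = as.numeric(e$value),
         weight = if (is.null(e$weight)) 1 else as.numeric(e$weight))
  })
  spec <- objective_spec(
    names = vapply(obj_rows, `[[`, "", "name"),
    observed = vapply(obj_rows, `[[`, 0, "value"),
    weights = vapply(obj_rows, `[[`, 0, "weight"))

  structure(list(group = doc$group, space = space, spec = spec,
                 settings = settings),
            class = "cnm_scenario")
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.cnm_scenario <- function(x, ...) {
  cat("Scenario ", x$group, ": ", n_free(x$space), " free parameters, ",
      length(x$spec$names), " objectives, horizon ", x$settings$t_end,
      " min\n", sep = "")
  invisible(x)
}

#' Write a scenario back to YAML
#'
#' Inverse of [load_config()]; `load_config(dump_config(sc, f))` returns a
#' scenario identical to `sc`.
#'
#' @param scenario a `cnm_scenario`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "cnm_scenario"))
  sp <- scenario$space; ob <- scenario$spec; st <- scenario$settings
  pars <- lapply(seq_along(sp$names), function(i) {
    if (sp$fixed_mask[i]) {
      list(id = i, name = sp$names[i], unit = sp$units[i],
           fixed = TRUE, value = sp$fixed_values[i])
    } else {
      list(id = i, name = sp$names[i], unit = sp$units[i],
           min = sp$lower[i], max = sp$upper[i])
    }
  })
  objs <- lapply(seq_along(ob$names), function(i)
    list(id = i, name = ob$names[i], value = ob$observed[i]))
  doc <- list(schema = "cnmpk-scenario-1", group = scenario$group,
              dosing = list(dose = st$dose,
                            infusion_duration = st$infusion_duration,
                            Q_liver = st$Q_liver, V_liver = st$V_liver,
                            t_end = st$t_end,
                            n_bile_transit = st$n_bile_transit),
              parameters = pars, objectives = objs)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

scenario_file <- function(group) {
  f <- system.file("extdata", paste0(tolower(group), ".yaml"),
                   package = "cnmpk")
  if (f == "") stop("packaged scenario file for group ", group, " not found")
  f
}

#' Packaged irinotecan study scenarios
#'
#' Convenience accessors for the shipped `oc.yaml` / `bdc.yaml` scenario
#' files.
#'
#' @param group `"OC"` or `"BDC"`.
#' @return `pbpk_scenario()`: the full `cnm_scenario`;
#'   `pbpk_parameter_space()`: its [parameter_space()];
#'   `pbpk_objectives()`: its [objective_spec()].
#' @export
pbpk_scenario <- function(group = c("OC", "BDC")) {
  group <- match.arg(group)
  load_config(scenario_file(group))
}

#' @rdname pbpk_scenario
#' @export
pbpk_parameter_space <- function(group = c("OC", "BDC")) {
  pbpk_scenario(group)$space
}

#' @rdname pbpk_scenario
#' @export
pbpk_objectives <- function(group = c("OC", "BDC")) {
  pbpk_scenario(group)$spec
}
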