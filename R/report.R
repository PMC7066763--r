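# Structured clinical-style reporting: unit-annotated result bundle,
# JSON (canonical) and markdown (human) renderings, serial comparison.

pkg_version <- function() as.character(utils::packageVersion("cmrquant"))

qval <- function(value, units, method = NULL)
  list(value = value, units = units, method = method)

#' Assemble a structured report bundle
#'
#' Collects module results into one schema-stable, unit-annotated bundle
#' with methods provenance and aggregated QC warnings.  Missing acquisition
#' metadata is rendered as explicit "not provided" entries rather than
#' omitted.  Duplicate blocks of the same kind are rejected.
#'
#' @param subject optional [subject()].
#' @param lv,rv `ventricular_result` blocks.
#' @param scar a `scar_result`.
#' @param perfusion list of `perfusion_metrics` / reserve indices.
#' @param t1_map,t2_map `map_result` blocks.
#' @param ecv an `ecv_result`.
#' @param t2star a `t2star_fit`.
#' @param t2w output of [t2w_si_ratio()].
#' @param flow a `flow_result`.
#' @param acquisition free-form list (sequence, field strength, contrast
#'   agent/dose) quoted in the report.
#' @param config list of analysis configuration to echo.
#' @return object of class `report_bundle`.
#' @export
assemble_report <- function(subject = NULL, lv = NULL, rv = NULL,
                            scar = NULL, perfusion = NULL, t1_map = NULL,
                            t2_map = NULL, ecv = NULL, t2star = NULL,
                            t2w = NULL, flow = NULL, acquisition = list(),
                            config = list()) {
  blocks <- list(lv = lv, rv = rv, scar = scar, perfusion = perfusion,
                 t1_map = t1_map, t2_map = t2_map, ecv = ecv,
                 t2star = t2star, t2w = t2w, flow = flow)
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (!length(blocks)) stop("at least one result block is required")
  if (anyDuplicated(names(blocks))) stop("conflicting duplicate blocks")
  qc <- character()
  out <- list(schema = "cmrquant-report", version = pkg_version(),
              subject = if (is.null(subject)) "not provided" else
                unclass(subject),
              acquisition = if (length(acquisition)) acquisition else
                "not provided",
              results = list(), methods = list(), qc = character())
  grab_warn <- function(x) {
    if (is.list(x) && !is.null(x$warnings)) qc <<- c(qc, x$warnings)
    if (is.list(x) && !is.null(x$qc)) qc <<- c(qc, x$qc)
  }
  for (nm in names(blocks)) grab_warn(blocks[[nm]])

  fmt_vent <- function(v) list(
    edv = qval(v$edv, "ml", v$method), esv = qval(v$esv, "ml", v$method),
    sv = qval(v$sv, "ml", v$method), ef = qval(v$ef, "%", v$method),
    co = if (is.null(v$co)) "not provided" else qval(v$co, "L/min", v$method),
    mass = if (is.null(v$mass_ed)) "not provided" else
      qval(v$mass_ed, "g", v$method),
    indexed = if (is.null(v$indexed)) "not provided" else v$indexed,
    papillary_mode = v$papillary_mode, phases = v$phases)
  if (!is.null(blocks$lv)) out$results$lv <- fmt_vent(blocks$lv)
  if (!is.null(blocks$rv)) out$results$rv <- fmt_vent(blocks$rv)
  if (!is.null(blocks$scar)) {
    s <- blocks$scar
    out$results$scar <- list(
      method = s$method,
      n_sd = if (identical(s$method, "n_sd")) s$n_sd else NULL,
      threshold = qval(s$threshold, "SI"),
      scar_mass = if (is.null(s$scar_mass_g)) "not provided" else
        qval(s$scar_mass_g, "g"),
      scar_fraction = if (is.null(s$scar_fraction_pct)) "not provided" else
        qval(s$scar_fraction_pct, "% of LV mass"),
      no_reflow_included = s$no_reflow_included)
  }
  if (!is.null(blocks$perfusion)) out$results$perfusion <- blocks$perfusion
  fmt_map <- function(m, what) list(
    value = qval(m$value, "ms", what), sd = qval(m$sd, "ms"),
    z = if (is.null(m$z)) "not provided" else qval(m$z, "SD"),
    normal_range = if (is.null(m$reference)) "not provided" else
      qval(m$reference$range, "ms"),
    reference = if (is.null(m$reference)) "not provided" else
      unclass(m$reference),
    n_pixels = m$roi$n_pixels)
  if (!is.null(blocks$t1_map))
    out$results$t1_map <- fmt_map(blocks$t1_map, "t1_roi")
  if (!is.null(blocks$t2_map))
    out$results$t2_map <- fmt_map(blocks$t2_map, "t2_roi")
  if (!is.null(blocks$ecv))
    out$results$ecv <- list(value = qval(blocks$ecv$ecv, "%", "delta_r1_ratio"),
                            inputs = blocks$ecv$inputs)
  if (!is.null(blocks$t2star)) {
    f <- blocks$t2star
    out$results$t2star <- list(
      value = qval(f$t2star, "ms", "monoexp_truncation"),
      flags = if (length(f$flags)) f$flags else "none",
      interpretation = if ("high_risk" %in% f$flags)
        "iron overload, increased heart-failure risk (T2* < 10 ms)"
      else if ("iron_overload" %in% f$flags)
        "cardiac iron overload (T2* < 20 ms)"
      else "within normal range",
      reference = qval(f$reference_normal_ms, "ms (normal, 1.5 T)"),
      truncated_echoes = f$truncated_count, fit_r2 = f$fit_r2)
  }
  if (!is.null(blocks$t2w))
    out$results$t2w <- list(
      ratio = qval(blocks$t2w$ratio, "myo/skeletal SI"),
      edema_positive = blocks$t2w$edema_positive,
      cutoff = qval(blocks$t2w$cutoff, "ratio"))
  if (!is.null(blocks$flow)) {
    fl <- blocks$flow
    out$results$flow <- list(
      antegrade = qval(fl$antegrade_ml, "ml"),
      retrograde = qval(fl$retrograde_ml, "ml"),
      net = qval(fl$net_ml, "ml"),
      regurgitant_fraction = qval(fl$regurgitant_fraction_pct, "%"),
      cardiac_output = if (is.null(fl$cardiac_output_l_min)) "not provided"
        else qval(fl$cardiac_output_l_min, "L/min"),
      cardiac_index = if (is.null(fl$cardiac_index_l_min_m2)) "not provided"
        else qval(fl$cardiac_index_l_min_m2, "L/min/m2"),
      peak_velocity = qval(fl$peak_velocity_cm_s, "cm/s",
                           fl$peak_convention),
      mean_velocity = qval(fl$mean_velocity_cm_s, "cm/s"),
      sign_convention = fl$sign_convention)
  }
  out$methods <- c(list(
    software = paste0("cmrquant ", pkg_version()),
    bsa_formula = if (!is.null(subject)) subject$bsa_formula else
      "not provided"), config)
  out$qc <- unique(qc)
  structure(out, class = "report_bundle")
}

#' Serialize a report bundle to JSON
#' @param bundle a `report_bundle`.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(bundle, path = NULL) {
  js <- jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE,
                         digits = I(17), null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse a report bundle back from JSON (lossless round-trip)
#' @param json JSON string or file path.
#' @return a `report_bundle`.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(x, class = "report_bundle")
}

# flatten numeric value/units leaves of a bundle to "path" -> value
flatten_values <- function(x, prefix = character()) {
  out <- list()
  if (is.list(x) && !is.null(x$value) && is.numeric(x$value) &&
      length(x$value) == 1) {
    key <- paste(prefix, collapse = ".")
    out[[key]] <- list(value = x$value, units = x$units,
                       method = x$method %||% NA_character_)
    return(out)
  }
  if (is.list(x))
    for (nm in names(x))
      out <- c(out, flatten_values(x[[nm]], c(prefix, nm)))
  out
}

#' Compare two report bundles parameter by parameter
#'
#' Serial evaluation requires consistent methods; any parameter whose
#' method tag differs between studies is flagged "method mismatch" rather
#' than differenced.
#'
#' @param current,prior `report_bundle`s.
#' @return data.frame: parameter, current, prior, change, change_pct,
#'   units, flag.
#' @export
compare_serial <- function(current, prior) {
  cv <- flatten_values(current$results, "results")
  pv <- flatten_values(prior$results, "results")
  keys <- intersect(names(cv), names(pv))
  rows <- lapply(keys, function(k) {
    a <- cv[[k]]; b <- pv[[k]]
    mismatch <- !identical(a$method, b$method)
    data.frame(parameter = k, current = a$value, prior = b$value,
               change = if (mismatch) NA_real_ else a$value - b$value,
               change_pct = if (mismatch || b$value == 0) NA_real_ else
                 100 * (a$value - b$value) / b$value,
               units = a$units %||% "",
               flag = if (mismatch) "method mismatch" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a report bundle as markdown
#' @param bundle a `report_bundle`.
#' @return character vector of markdown lines.
#' @export
render_report_md <- function(bundle) {
  ln <- c("# CMR quantitative report",
          sprintf("_software: %s_", bundle$methods$software), "")
  vals <- flatten_values(bundle$results, character())
  ln <- c(ln, "| parameter | value | units | method |",
          "|---|---|---|---|")
  for (k in names(vals)) {
    v <- vals[[k]]
    ln <- c(ln, sprintf("| %s | %.4g | %s | %s |", k, v$value,
                        v$units %||% "", v$method %||% ""))
  }
  if (!is.null(bundle$results$t2star))
    ln <- c(ln, "", sprintf("T2*: %s (normal ~%g ms).",
                            bundle$results$t2star$interpretation,
                            bundle$results$t2star$reference$value))
  if (!is.null(bundle$results$lv) &&
      grepl("area_length", bundle$results$lv$edv$method %||% ""))
    ln <- c(ln, "", sprintf("Analysis technique: %s (area-length rapid method).",
                            bundle$results$lv$edv$method))
  if (length(bundle$qc))
    ln <- c(ln, "", "## QC", paste0("- ", bundle$qc))
  ln
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
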