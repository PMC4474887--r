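# Figure-style panel rendering (every plotted number also lands in a CSV
# twin) and run provenance records.

panel_doses <- c(0, 0.1, 1, 5, 10)

# Long data.frame of one species across the panel doses of a scan.
scan_long <- function(scan, species, doses = NULL) {
  if (is.null(doses)) doses <- scan$doses
  out <- list()
  for (d in doses) {
    i <- match(d, scan$doses)
    if (is.na(i))
      stop(sprintf("dose %g Gy is not in the scan; run the scan with it",
                   d), call. = FALSE)
    s <- scan_series(scan, i, species)
    out[[length(out) + 1L]] <- data.frame(dose_gy = d, species = species,
                                          s)
  }
  do.call(rbind, out)
}

save_panel <- function(plt, df, stem, out_dir, format, width, height) {
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  img <- file.path(out_dir, paste0(stem, ".", format))
  ggplot2::ggsave(img, plt, width = width, height = height, dpi = 150)
  c(img, csv)
}

#' Render figure-style panels with CSV twins
#'
#' Renders the standard result views; every number that is plotted is also
#' written to a CSV file of the same stem, so no value exists only inside
#' an image.
#'
#' \describe{
#'   \item{fig2}{p53 and Mdm2 time courses at doses 0, 0.1, 1, 5, 10 Gy
#'     (needs a \code{ccm_scan} containing those doses).}
#'   \item{fig3}{phase-diagram maxima scatter and, if a collapse curve is
#'     supplied, the collapse-time-versus-dose inset (needs a
#'     \code{ccm_phase_diagram}; optionally a \code{ccm_collapse_curve}).}
#'   \item{fig4, fig5}{cyclin (fig4) or MPF (fig5) time courses and
#'     time-resolved maxima scatters at the five standard doses (needs a
#'     \code{ccm_scan}).}
#'   \item{fig6}{maxima versus dose for MPF and cyclin over a fixed time
#'     window (needs a \code{ccm_scan}).}
#' }
#'
#' @param results Named list of upstream results: \code{scan},
#'   \code{phase}, \code{collapse} as required by the panel.
#' @param which One of \code{"fig2"}, \code{"fig3"}, \code{"fig4"},
#'   \code{"fig5"}, \code{"fig6"}.
#' @param out_dir Output directory (created if missing).
#' @param format Image format understood by [ggplot2::ggsave()]
#'   (\code{"png"}, \code{"svg"}, \code{"pdf"}).
#' @param width,height Image size in inches.
#' @return Character vector of files written (images and CSV twins),
#'   invisibly.
#' @export
render_panels <- function(results, which = c("fig2", "fig3", "fig4",
                                             "fig5", "fig6"),
                          out_dir = ".", format = "png", width = 8,
                          height = 9) {
  which <- match.arg(which)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(name, class, cmd) {
    x <- results[[name]]
    if (is.null(x) || !inherits(x, class))
      stop(sprintf("panel %s needs results$%s (a %s); produce it with %s",
                   which, name, class, cmd), call. = FALSE)
    x
  }
  aes <- ggplot2::aes
  files <- switch(which,
    fig2 = {
      scan <- need("scan", "ccm_scan", "run_dose_scan()")
      df <- rbind(scan_long(scan, "p53", panel_doses),
                  scan_long(scan, "mdm2", panel_doses))
      plt <- ggplot2::ggplot(df, aes(time_h, value)) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::facet_grid(dose_gy ~ species, scales = "free_y",
                            labeller = ggplot2::label_both) +
        ggplot2::labs(x = "time (h)", y = "concentration (arb. units)")
      save_panel(plt, df, "fig2_p53_mdm2_timecourses", out_dir, format,
                 width, height)
    },
    fig3 = {
      ph <- need("phase", "ccm_phase_diagram", "phase_boundary()")
      df <- ph$maxima
      plt <- ggplot2::ggplot(df, aes(time_h, value, colour = dose_gy)) +
        ggplot2::geom_point(size = 0.4) +
        ggplot2::labs(x = "time (h)", y = "late-window p53 maxima",
                      colour = "IR (Gy)")
      f1 <- save_panel(plt, df, "fig3_phase_maxima", out_dir, format,
                       width, height * 0.6)
      f2 <- character(0)
      if (!is.null(results$collapse)) {
        cc <- need("collapse", "ccm_collapse_curve", "collapse_curve()")
        d2 <- as.data.frame(cc)
        p2 <- ggplot2::ggplot(d2[!d2$censored, ], aes(dose_gy, dt_h)) +
          ggplot2::geom_point() + ggplot2::geom_line() +
          ggplot2::labs(x = "IR (Gy)", y = "collapse time (h)")
        f2 <- save_panel(p2, d2, "fig3_collapse_curve", out_dir, format,
                         width * 0.6, height * 0.5)
      }
      c(f1, f2)
    },
    fig4 = ,
    fig5 = {
      scan <- need("scan", "ccm_scan", "run_dose_scan()")
      sp <- if (which == "fig4") "cyclin" else "mpf"
      df <- scan_long(scan, sp, panel_doses)
      plt <- ggplot2::ggplot(df, aes(time_h, value)) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::facet_grid(dose_gy ~ ., scales = "free_y",
                            labeller = ggplot2::label_both) +
        ggplot2::labs(x = "time (h)", y = sp)
      f1 <- save_panel(plt, df, paste0(which, "_", sp, "_timecourses"),
                       out_dir, format, width, height)
      mx <- do.call(rbind, lapply(panel_doses, function(d) {
        i <- match(d, scan$doses)
        m <- find_maxima(scan_series(scan, i, sp), transient_h = 0)
        if (!nrow(m)) return(NULL)
        data.frame(dose_gy = d, as.data.frame(m))
      }))
      p2 <- ggplot2::ggplot(mx, aes(time_h, value)) +
        ggplot2::geom_point(size = 0.3) +
        ggplot2::facet_grid(dose_gy ~ ., scales = "free_y",
                            labeller = ggplot2::label_both) +
        ggplot2::labs(x = "time (h)", y = paste(sp, "maxima"))
      c(f1, save_panel(p2, mx, paste0(which, "_", sp, "_bifurcation"),
                       out_dir, format, width, height))
    },
    fig6 = {
      scan <- need("scan", "ccm_scan", "run_dose_scan()")
      tw <- c(0, min(50, scan$horizon_h))
      df <- rbind(data.frame(species = "mpf",
                             maxima_vs_dose(scan, "mpf", tw)),
                  data.frame(species = "cyclin",
                             maxima_vs_dose(scan, "cyclin", tw)))
      plt <- ggplot2::ggplot(df, aes(dose_gy, value)) +
        ggplot2::geom_point(size = 0.3) +
        ggplot2::facet_grid(species ~ ., scales = "free_y") +
        ggplot2::labs(x = "IR (Gy)",
                      y = sprintf("maxima in [%g, %g] h", tw[1], tw[2]))
      save_panel(plt, df, "fig6_maxima_vs_dose", out_dir, format, width,
                 height * 0.7)
    })
  invisible(files)
}

# Stable md5 of a configuration list (canonical JSON via a temp file).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a run-provenance record
#'
#' JSON record of a run: configuration hash, parameter set, typo-policy
#' flags, package version, per-stage timings and the output-file
#' inventory.  Re-running with the same configuration reproduces the same
#' hash; any parameter change changes it.
#'
#' @param params A \code{ccm_params}.
#' @param path Output JSON path.
#' @param config Further configuration entering the hash (doses, horizon,
#'   control settings, seeds), as a named list.
#' @param outputs Character vector of output files to inventory.
#' @param timings Named numeric vector of per-stage timings (seconds).
#' @return The record, invisibly (written to \code{path}).
#' @export
write_run_record <- function(params, path, config = list(),
                             outputs = character(0),
                             timings = numeric(0)) {
  stopifnot(inherits(params, "ccm_params"))
  kn <- setdiff(.k_names, .k_composite)
  full_config <- c(params[kn], list(typo_policy = params$typo_policy),
                   config)
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("outputs not on disk: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec <- list(
    config_hash = config_hash(full_config),
    parameters = params[kn],
    typo_policy = params$typo_policy,
    config = config,
    package_version = as.character(utils::packageVersion("p53cycle")),
    timings_s = as.list(timings),
    outputs = lapply(outputs, function(f)
      list(file = f, bytes = file.size(f)))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rec)
}
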