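## Packaged IGF-1R / ER-alpha signaling networks.
##
## Two continuous Petri nets reconstruct the published untreated (diseased)
## and fulvestrant-treated networks: the IGF -> IGF-1R -> IRS-1 -> PI3k ->
## Akt -> ER-alpha cascade, the ER-alpha positive feedback onto IGF-1R,
## ER-alpha inhibition of the tumor-suppressor program (p53, BRCA1, Mdm2),
## Mdm2-mediated p53 degradation, and - in the treated net - a constant
## fulvestrant place inhibiting IGF-1R/IRS-1/ER-alpha activation plus a PTEN
## branch restoring the suppressors.  All transitions are mass action with
## rate 1 and unit arc weights; every signaling species carries a first-order
## degradation transition so trajectories stay bounded.  IGF starts at 5
## tokens; the remaining initial markings are free parameters of the
## reconstruction, calibrated once (and then frozen) so that the default
## discretization thresholds reproduce the published qualitative table:
## receptor/kinase places 4, ER-alpha 3, suppressed TSG baseline 0.2-0.5,
## fulvestrant 5 (the ligand scale).

.igfr_places_untreated <- function() {
  data.frame(
    name = c("IGF", "IGF-1R", "IRS-1", "PI3k", "Akt", "ER-alpha",
             "p53", "BRCA1", "Mdm2"),
    initial = c(5, 4, 4, 4, 4, 3, 0.2, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

.ma <- function(name, source = FALSE) {
  data.frame(name = name, type = "mass_action", k = 1,
             Vmax = NA_real_, Km = NA_real_, source = source,
             stringsAsFactors = FALSE)
}

.arc <- function(place, transition, direction, weight = 1) {
  data.frame(place = place, transition = transition, direction = direction,
             weight = weight, stringsAsFactors = FALSE)
}

.catalytic <- function(trans, catalyst, product) {
  rbind(.arc(catalyst, trans, "pre"), .arc(catalyst, trans, "post"),
        .arc(product, trans, "post"))
}

#' Build the untreated (diseased) IGF-1R network
#'
#' @return a validated [hybrid_petri_net()].
#' @export
build_untreated <- function() {
  places <- .igfr_places_untreated()
  transitions <- rbind(
    .ma("act_IGF-1R"), .ma("act_IRS-1"), .ma("act_PI3k"), .ma("act_Akt"),
    .ma("act_ER-alpha"), .ma("fb_ER-alpha_IGF-1R"),
    .ma("act_p53", source = TRUE), .ma("act_Mdm2", source = TRUE),
    .ma("act_BRCA1"), .ma("deg_p53_Mdm2"),
    .ma("deg_IGF-1R"), .ma("deg_IRS-1"), .ma("deg_PI3k"), .ma("deg_Akt"),
    .ma("deg_ER-alpha"), .ma("deg_p53"), .ma("deg_BRCA1"), .ma("deg_Mdm2"))
  arcs <- rbind(
    .catalytic("act_IGF-1R", "IGF", "IGF-1R"),
    .catalytic("act_IRS-1", "IGF-1R", "IRS-1"),
    .catalytic("act_PI3k", "IRS-1", "PI3k"),
    .catalytic("act_Akt", "PI3k", "Akt"),
    .catalytic("act_ER-alpha", "Akt", "ER-alpha"),
    # positive feedback: active ER-alpha engages IGF-1R transcription
    .arc("ER-alpha", "fb_ER-alpha_IGF-1R", "pre"),
    .arc("IGF-1R", "fb_ER-alpha_IGF-1R", "post"),
    .arc("p53", "act_p53", "post"),
    .arc("Mdm2", "act_Mdm2", "post"),
    .catalytic("act_BRCA1", "Mdm2", "BRCA1"),
    # Mdm2-mediated p53 degradation (Mdm2 conserved)
    .arc("p53", "deg_p53_Mdm2", "pre"), .arc("Mdm2", "deg_p53_Mdm2", "pre"),
    .arc("Mdm2", "deg_p53_Mdm2", "post"),
    .arc("IGF-1R", "deg_IGF-1R", "pre"),
    .arc("IRS-1", "deg_IRS-1", "pre"),
    .arc("PI3k", "deg_PI3k", "pre"),
    .arc("Akt", "deg_Akt", "pre"),
    .arc("ER-alpha", "deg_ER-alpha", "pre"),
    .arc("p53", "deg_p53", "pre"),
    .arc("BRCA1", "deg_BRCA1", "pre"),
    .arc("Mdm2", "deg_Mdm2", "pre"))
  inhibitory <- data.frame(
    place = rep("ER-alpha", 3),
    transition = c("act_p53", "act_Mdm2", "act_BRCA1"),
    threshold = 1, stringsAsFactors = FALSE)
  net <- hybrid_petri_net(places, transitions, arcs, inhibitory)
  net$comment <- paste(
    "Untreated (diseased) IGF-1R network reconstruction.",
    "Interactions: IGF->IGF-1R->IRS-1->PI3k->Akt->ER-alpha activation cascade",
    "(catalytic, upstream place conserved); ER-alpha positive feedback onto",
    "IGF-1R (consumes active ER-alpha); ER-alpha inhibitory arcs on each TSG",
    "activation (p53, Mdm2, BRCA1); Mdm2 catalyses BRCA1 activation and",
    "mediates p53 degradation; first-order degradation on every signaling",
    "species. All mass-action rates 1, unit weights, thresholds 1. Initial",
    "markings: IGF 5 (stated); receptor/kinases 4, ER-alpha 3, TSGs 0.2-0.5",
    "(calibrated once against the published qualitative table, then frozen).")
  stopifnot(length(validate_net(net)) == 0L)
  net
}

#' Build the fulvestrant-treated IGF-1R network
#'
#' The untreated net plus a constant fulvestrant place (marking 5) with
#' inhibitory arcs on the IGF-1R, IRS-1 and ER-alpha activation transitions
#' (including the ER-alpha feedback onto IGF-1R), and a PTEN branch:
#' homeostatic PTEN/Mdm2 activation once ER-alpha falls below threshold,
#' p53-driven PTEN production, and PTEN inhibition of PI3k/Akt activation.
#'
#' @return a validated [hybrid_petri_net()].
#' @export
build_treated <- function() {
  net <- build_untreated()
  net$places <- rbind(net$places,
                      data.frame(name = c("fulvestrant", "PTEN"),
                                 initial = c(5, 0.5)))
  net$transitions <- rbind(net$transitions,
                           .ma("act_PTEN", source = TRUE),
                           .ma("act_PTEN_p53"),
                           .ma("act_Mdm2_PTEN"),
                           .ma("deg_PTEN"))
  net$arcs <- rbind(net$arcs,
                    .arc("PTEN", "act_PTEN", "post"),
                    .catalytic("act_PTEN_p53", "p53", "PTEN"),
                    .catalytic("act_Mdm2_PTEN", "PTEN", "Mdm2"),
                    .arc("PTEN", "deg_PTEN", "pre"))
  net$inhibitory_arcs <- rbind(
    net$inhibitory_arcs,
    data.frame(place = "fulvestrant",
               transition = c("act_IGF-1R", "fb_ER-alpha_IGF-1R",
                              "act_IRS-1", "act_ER-alpha"),
               threshold = 1),
    # the homeostatic TSG program is suppressed while ER-alpha signaling is up
    data.frame(place = "ER-alpha",
               transition = c("act_PTEN", "act_Mdm2_PTEN"),
               threshold = 1),
    data.frame(place = "PTEN",
               transition = c("act_PI3k", "act_Akt"),
               threshold = 1))
  net$comment <- paste(
    "Fulvestrant-treated IGF-1R network: the untreated reconstruction plus a",
    "constant fulvestrant boundary place (marking 5, the ligand scale) with",
    "inhibitory arcs on IGF-1R, IRS-1 and ER-alpha activation (including the",
    "ER-alpha feedback onto IGF-1R), and a PTEN branch: homeostatic PTEN and",
    "PTEN->Mdm2 activation released once ER-alpha falls below threshold,",
    "p53-catalysed PTEN production, PTEN inhibitory arcs on PI3k/Akt",
    "activation, first-order PTEN degradation. With fulvestrant at 0 and",
    "PTEN below threshold the shared-place vector field equals the untreated",
    "net's.")
  stopifnot(length(validate_net(net)) == 0L)
  net
}

#' Simulate a net over the standard scenario horizons
#'
#' @param net a [hybrid_petri_net()].
#' @param horizons vector of horizons in time units (default 10, 50, 100).
#' @param ... passed to [simulate_net()].
#' @return named list of `pn_trajectory` objects (`"10"`, `"50"`, ...).
#' @export
run_scenarios <- function(net, horizons = c(10, 50, 100), ...) {
  stats::setNames(lapply(horizons, function(h) simulate_net(net, h, ...)),
                  as.character(horizons))
}

#' Discretize fold changes into the qualitative comparison table
#'
#' Per protein and condition the end-of-run fold change
#' (final marking / initial marking) is discretized: `>= t_high` into
#' `"+++"`, `[t_mid, t_high)` into `"++"`, `<= t_low` into `"---"`.
#' Intermediate values keep their number, get symbol `"+/-"` and raise a
#' warning.  Defaults (2.0 / 1.2 / 0.5) are frozen.
#'
#' @param untreated,treated `pn_trajectory` objects covering `proteins`.
#' @param proteins place names to report.
#' @param t_high,t_mid,t_low discretization thresholds.
#' @return data.frame with columns `protein`, `untreated_fold`,
#'   `untreated_symbol`, `treated_fold`, `treated_symbol`.
#' @export
qualitative_profile <- function(untreated, treated,
                                proteins = c("IGF-1R", "IRS-1", "ER-alpha"),
                                t_high = 2.0, t_mid = 1.2, t_low = 0.5) {
  for (traj in list(untreated, treated)) {
    missing <- setdiff(proteins, colnames(traj$markings))
    if (length(missing)) {
      stop("trajectory does not cover protein(s): ",
           paste(missing, collapse = ", "))
    }
  }
  symbolize <- function(f, protein) {
    if (is.na(f)) return("+/-")
    if (f >= t_high) "+++"
    else if (f >= t_mid) "++"
    else if (f <= t_low) "---"
    else {
      warning("fold change ", format(f, digits = 3), " of '", protein,
              "' falls in no band; reported as '+/-'")
      "+/-"
    }
  }
  rows <- lapply(proteins, function(p) {
    fu <- fold_change(untreated, p, "final_over_initial")
    ft <- fold_change(treated, p, "final_over_initial")
    data.frame(protein = p,
               untreated_fold = fu, untreated_symbol = symbolize(fu, p),
               treated_fold = ft, treated_symbol = symbolize(ft, p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot untreated vs treated marking curves, one panel per protein
#'
#' @param untreated,treated `pn_trajectory` objects.
#' @param proteins place names to plot.
#' @param file optional PNG output path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_comparison <- function(untreated, treated,
                            proteins = c("ER-alpha", "IGF-1R", "p53", "BRCA1",
                                         "Mdm2", "Akt", "PI3k", "IRS-1"),
                            file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 1200, height = 900)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(proteins)),
                       mar = c(4, 4, 2, 1))
  on.exit({
    graphics::par(old)
    if (!is.null(file)) grDevices::dev.off()
  })
  for (p in proteins) {
    yu <- untreated$markings[, p]
    yt <- if (p %in% colnames(treated$markings)) treated$markings[, p] else NULL
    ylim <- range(c(yu, yt), na.rm = TRUE)
    graphics::plot(untreated$time, yu, type = "l", lwd = 2, ylim = ylim,
                   xlab = "time (units)", ylab = "marking (tokens)", main = p)
    if (!is.null(yt)) {
      graphics::lines(treated$time, yt, lwd = 2, col = "darkgreen")
    }
    graphics::legend("topright", c("untreated", "treated"), lwd = 2,
                     col = c("black", "darkgreen"), bty = "n", cex = 0.8)
  }
  invisible(file)
}
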