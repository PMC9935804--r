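# Static morphology: 35 features measured at the reference frame (the third
# frame before pronucleus fading, ~1 h prior to tPNf), from geometry
# annotations of the ooplasm, zona pellucida, pronuclei (PN) and nucleolus
# precursor bodies (NPB).

#' Construct a geometry annotation
#'
#' Coordinates are image pixels, origin top-left, x rightward, y downward.
#' Any component may be `NULL`/`NA` (missingness is data, not an error), but
#' supplied radii must be positive and NPB coordinates must lie inside their
#' PN disc.
#'
#' @param oo_center length-2 ooplasm centre (x, y).
#' @param oo_radius ooplasm radius R_o.
#' @param zona_inner,zona_outer zona pellucida inner/outer radii.
#' @param pn_small,pn_large lists with `center` (x, y) and `radius`; the
#'   small PN radius must not exceed the large one.
#' @param npb_small,npb_large n x 2 matrices of NPB coordinates per PN.
#' @param frag_2c,frag_4c fragmentation percentage at the 2- and 4-cell stage.
#' @param sym_2c,sym_4c blastomere-size symmetry grade at 2C / 4C.
#' @param cleavage_angle first-cleavage-plane orientation in degrees
#'   (consumed as an annotated scalar).
#' @return object of class `geometry_annotation`.
#' @export
geometry_annotation <- function(oo_center = NULL, oo_radius = NA,
                                zona_inner = NA, zona_outer = NA,
                                pn_small = NULL, pn_large = NULL,
                                npb_small = NULL, npb_large = NULL,
                                frag_2c = NA, frag_4c = NA,
                                sym_2c = NA, sym_4c = NA,
                                cleavage_angle = NA) {
  chk_r <- function(r, what) {
    if (length(r) && !all(is.na(r)) && any(r[!is.na(r)] <= 0))
      stop(what, " radius must be positive")
  }
  chk_r(oo_radius, "ooplasm"); chk_r(zona_inner, "zona inner")
  chk_r(zona_outer, "zona outer")
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- matrix(as.numeric(m), ncol = 2)
    m
  }
  npb_small <- as_mat(npb_small); npb_large <- as_mat(npb_large)
  for (side in c("small", "large")) {
    pn <- get(paste0("pn_", side))
    npb <- get(paste0("npb_", side))
    if (!is.null(pn)) chk_r(pn$radius, paste(side, "PN"))
    if (!is.null(pn) && !is.null(npb) && nrow(npb) > 0 &&
        !is.na(pn$radius)) {
      d <- sqrt((npb[, 1] - pn$center[1])^2 + (npb[, 2] - pn$center[2])^2)
      if (any(d > pn$radius + 1e-9))
        stop("NPB coordinates outside the ", side, " PN disc")
    }
  }
  if (!is.null(pn_small) && !is.null(pn_large) &&
      !is.na(pn_small$radius) && !is.na(pn_large$radius) &&
      pn_small$radius > pn_large$radius + 1e-9)
    stop("small PN radius exceeds large PN radius")
  structure(list(oo_center = oo_center, oo_radius = oo_radius,
                 zona_inner = zona_inner, zona_outer = zona_outer,
                 pn_small = pn_small, pn_large = pn_large,
                 npb_small = npb_small, npb_large = npb_large,
                 frag_2c = frag_2c, frag_4c = frag_4c,
                 sym_2c = sym_2c, sym_4c = sym_4c,
                 cleavage_angle = cleavage_angle),
            class = "geometry_annotation")
}

max_pairwise_dist <- function(pts) {
  if (is.null(pts) || nrow(pts) == 0L) return(NA_real_)
  if (nrow(pts) == 1L) return(0)  # single point: empty pair set, 0 by convention
  max(stats::dist(pts))
}

mean_pairwise_dist <- function(pts) {
  if (is.null(pts) || nrow(pts) == 0L) return(NA_real_)
  if (nrow(pts) == 1L) return(0)
  mean(stats::dist(pts))
}

sd_pairwise_dist <- function(pts) {
  if (is.null(pts) || nrow(pts) < 3L) return(if (is.null(pts) || nrow(pts) == 0L) NA_real_ else 0)
  stats::sd(stats::dist(pts))
}

#' NPB count and spatial-distribution features
#'
#' Emits the 4 NPB-count features and the 11 NPB spatial features of the
#' catalog, including `f1 = (max_{i,j} d_ij) / R_PN`: the maximal pairwise
#' distance between NPBs of the small PN normalised by the small-PN radius.
#' A single NPB gives a maximal distance of 0 (empty pair set); zero NPBs
#' give a missing value, flagged, so "measurably compact" and "unmeasured"
#' stay distinct.
#'
#' @param geom a [geometry_annotation()].
#' @return named numeric vector of 15 values with a `flags` attribute.
#' @export
npb_features <- function(geom) {
  stopifnot(inherits(geom, "geometry_annotation"))
  ns <- geom$npb_small; nl <- geom$npb_large
  n_s <- if (is.null(ns)) NA_integer_ else nrow(ns)
  n_l <- if (is.null(nl)) NA_integer_ else nrow(nl)
  flags <- character(0)
  r_s <- if (is.null(geom$pn_small)) NA_real_ else geom$pn_small$radius
  r_l <- if (is.null(geom$pn_large)) NA_real_ else geom$pn_large$radius
  max_s <- max_pairwise_dist(ns)
  max_l <- max_pairwise_dist(nl)
  if (!is.na(n_s) && n_s == 0L) flags <- c(flags, "no NPBs in small PN: f1 missing")
  cross <- c(min = NA_real_, mean = NA_real_, max = NA_real_)
  if (!is.null(ns) && !is.null(nl) && nrow(ns) > 0 && nrow(nl) > 0) {
    dd <- sqrt(outer(ns[, 1], nl[, 1], "-")^2 + outer(ns[, 2], nl[, 2], "-")^2)
    cross <- c(min = min(dd), mean = mean(dd), max = max(dd))
  }
  out <- c(
    npb_n_small = as.numeric(n_s),
    npb_n_large = as.numeric(n_l),
    npb_n_total = as.numeric(n_s + n_l),
    npb_n_diff = as.numeric(n_l - n_s),
    npb_maxdist_small_norm = max_s / r_s,        # f1
    npb_maxdist_small = max_s,
    npb_meandist_small = mean_pairwise_dist(ns),
    npb_sddist_small = sd_pairwise_dist(ns),
    npb_maxdist_large_norm = max_l / r_l,
    npb_maxdist_large = max_l,
    npb_meandist_large = mean_pairwise_dist(nl),
    npb_sddist_large = sd_pairwise_dist(nl),
    npb_cross_min = cross[["min"]],
    npb_cross_mean = cross[["mean"]],
    npb_cross_max = cross[["max"]]
  )
  attr(out, "flags") <- flags
  out
}

#' The 35-feature static morphology catalog
#'
#' Computes, in fixed catalog order: blastomere-size symmetry at 2C/4C (2),
#' fragmentation percentage at 2C/4C (2), PN size features (7), PN location
#' features (3), NPB count distributions (4), NPB spatial distributions
#' within and between the PNs (11, including f1), the annotated
#' first-cleavage-plane orientation (1), and ooplasm / zona pellucida radii
#' (5, including f2 = ooplasm radius). Missing annotations propagate as
#' missing values.
#'
#' @param geom a [geometry_annotation()].
#' @return named numeric vector of exactly 35 values.
#' @export
morphology_catalog <- function(geom) {
  stopifnot(inherits(geom, "geometry_annotation"))
  g <- geom
  r_s <- if (is.null(g$pn_small)) NA_real_ else g$pn_small$radius
  r_l <- if (is.null(g$pn_large)) NA_real_ else g$pn_large$radius
  cdist <- function(pn) {
    if (is.null(pn) || is.null(g$oo_center)) return(NA_real_)
    sqrt(sum((pn$center - g$oo_center)^2))
  }
  pn_sep <- if (is.null(g$pn_small) || is.null(g$pn_large)) NA_real_ else
    sqrt(sum((g$pn_small$center - g$pn_large$center)^2))
  npb <- npb_features(g)
  out <- c(
    sym_2c = as.numeric(g$sym_2c),
    sym_4c = as.numeric(g$sym_4c),
    frag_2c = as.numeric(g$frag_2c),
    frag_4c = as.numeric(g$frag_4c),
    pn_r_small = r_s,
    pn_r_large = r_l,
    pn_area_small = pi * r_s^2,
    pn_area_large = pi * r_l^2,
    pn_r_ratio = r_s / r_l,
    pn_area_ratio = r_s^2 / r_l^2,
    pn_r_diff = r_l - r_s,
    pn_small_dist_center = cdist(g$pn_small),
    pn_large_dist_center = cdist(g$pn_large),
    pn_sep = pn_sep,
    npb,
    cleavage_angle = as.numeric(g$cleavage_angle),
    ooplasm_r = as.numeric(g$oo_radius),              # f2
    zona_inner_r = as.numeric(g$zona_inner),
    zona_outer_r = as.numeric(g$zona_outer),
    zona_thickness = as.numeric(g$zona_outer - g$zona_inner),
    pvs_width = as.numeric(g$zona_inner - g$oo_radius)
  )
  attr(out, "flags") <- attr(npb, "flags")
  stopifnot(length(out) == 35L)
  out
}

morphology_feature_names <- function() {
  c("sym_2c", "sym_4c", "frag_2c", "frag_4c",
    "pn_r_small", "pn_r_large", "pn_area_small", "pn_area_large",
    "pn_r_ratio", "pn_area_ratio", "pn_r_diff",
    "pn_small_dist_center", "pn_large_dist_center", "pn_sep",
    "npb_n_small", "npb_n_large", "npb_n_total", "npb_n_diff",
    "npb_maxdist_small_norm", "npb_maxdist_small", "npb_meandist_small",
    "npb_sddist_small", "npb_maxdist_large_norm", "npb_maxdist_large",
    "npb_meandist_large", "npb_sddist_large",
    "npb_cross_min", "npb_cross_mean", "npb_cross_max",
    "cleavage_angle",
    "ooplasm_r", "zona_inner_r", "zona_outer_r", "zona_thickness",
    "pvs_width")
}
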