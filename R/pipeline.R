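# One-call pipeline: BAM -> profile -> mixture fit -> hcTs -> MRN clusters.

#' Call RBP binding sites from a PAR-CLIP BAM in one step
#'
#' Convenience wrapper running the full method: build the substitution
#' profile, fit the RSF mixture (target transitions vs all other
#' substitution types at \code{fit_min_cov}), classify high-confidence
#' transitions at the posterior cutoff, build coverage tracks and call
#' clusters with the MRN algorithm.
#'
#' @param bam PAR-CLIP BAM path.
#' @param genome Reference genome (see \code{\link{load_genome}}).
#' @param subst Target transition (default \code{"TC"} for 4SU; \code{"GA"}
#'   for 6SG).
#' @param cutoff Posterior cutoff \eqn{\delta} (default 0.9).
#' @param fit_min_cov Minimum coverage for model fitting (default 20).
#' @param call_min_cov Minimum coverage at hcTs used for calling (default 20;
#'   set to 1 for exhaustive calling after fitting at 20).
#' @param cfg An \code{\link{mrn_config}}.
#' @param min_mapq Optional mapping-quality filter for ingestion.
#' @return List with \code{profile}, \code{model}, \code{hcts} (with
#'   \code{support} attribute), \code{tracks}, \code{clusters}.
#' @export
call_binding_sites <- function(bam, genome, subst = "TC", cutoff = 0.9,
                               fit_min_cov = 20L, call_min_cov = 20L,
                               cfg = mrn_config(), min_mapq = NULL) {
  genome <- load_genome(genome)
  profile <- substitution_profile(bam, genome, min_mapq = min_mapq)
  target <- extract_sites(profile, subst = subst, min_cov = fit_min_cov)
  bg <- background_sites(profile, target = subst, min_cov = fit_min_cov)
  model <- fit_rsf_mixture(target, bg, min_cov = fit_min_cov)
  sites_all <- if (call_min_cov == fit_min_cov) target else
    extract_sites(profile, subst = subst, min_cov = call_min_cov)
  hcts <- classify_hct(model, sites_all, cutoff = cutoff,
                       min_cov = call_min_cov)
  tracks <- coverage_tracks(bam, min_mapq = min_mapq)
  crosslink_base <- substr(subst, 1, 1)
  clusters <- call_clusters(tracks, hcts, genome, cfg = cfg,
                            crosslink_base = crosslink_base)
  list(profile = profile, model = model, hcts = hcts, tracks = tracks,
       clusters = clusters)
}
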