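#' Mineral lost during demineralization, from wet-weight change
#'
#' Mass balance for decalcifier treatment under buffer saturation: the volume
#' of dissolved mineral is replaced by an equal volume of medium, so a wet
#' weight change dW relates to mineral loss through the density difference,
#' \deqn{V_{M,lost} = \frac{\Delta W_{wet}}{\rho_W - \rho_M}, \qquad
#'       W_{M,lost} = \rho_M V_{M,lost}.}
#' Because the mineral (hydroxyapatite) is denser than the medium, a net
#' weight decrease (\code{deltaWwet <= 0}) implies a positive mineral loss.
#'
#' @param deltaWwet wet-weight change in g, after minus before; must be
#'   \code{<= 0} under the model assumption. May be a vector.
#' @param rhoM mineral (hydroxyapatite) density, g/cm^3; default 3.16.
#' @param rhoW medium (water/buffer) density, g/cm^3; default 1.00.
#' @return list with \code{vLost} (cm^3) and \code{wLost} (g), both >= 0.
#' @examples
#' mineralLost(-0.216)   # vLost 0.1 cm^3, wLost 0.316 g
#' @export
mineralLost <- function(deltaWwet, rhoM = 3.16, rhoW = 1.00) {
  if (!is.numeric(rhoM) || !is.numeric(rhoW) || rhoM <= 0 || rhoW <= 0)
    stop("densities must be positive")
  if (rhoM == rhoW)
    stop("degenerate densities: rhoM must differ from rhoW")
  if (any(deltaWwet > 0))
    stop("deltaWwet must be <= 0 (wet weight cannot increase under the model)")
  vLost <- deltaWwet / (rhoW - rhoM)
  list(vLost = vLost, wLost = rhoM * vLost)
}

#' Remaining mineral content as weight percent
#'
#' @param wLostCumulative cumulative mineral mass lost, g (vectorized).
#' @param wMineralInitial mineral mass of the intact sample, g.
#' @return wt% of mineral remaining, in [0, 100].
#' @examples
#' mineralContentPercent(c(0, 0.4, 1), 1)   # 100, 60, 0
#' @export
mineralContentPercent <- function(wLostCumulative, wMineralInitial) {
  if (!is.numeric(wMineralInitial) || wMineralInitial <= 0)
    stop("wMineralInitial must be > 0")
  if (any(wLostCumulative < 0))
    stop("cumulative loss cannot be negative")
  if (any(wLostCumulative > wMineralInitial * (1 + 1e-12)))
    stop("cumulative loss exceeds the initial mineral mass")
  100 * (1 - wLostCumulative / wMineralInitial)
}

#' Mineral-content trajectory from a weighing record table
#'
#' Converts serial wet weights of demineralized samples into remaining
#' mineral wt%. Input columns: \code{sample_id}, \code{timepoint_h},
#' \code{w_wet_g}. For each sample the weight change relative to the first
#' timepoint is converted by [mineralLost()] and scaled by the intact mineral
#' mass.
#'
#' @param records data.frame of weighing records.
#' @param wMineralInitial intact mineral mass in g: a single value or a named
#'   vector keyed by sample id.
#' @param rhoM,rhoW densities as in [mineralLost()].
#' @return data.frame of records with added columns \code{w_lost_g} and
#'   \code{mineral_wt_percent}.
#' @export
mineralTrajectory <- function(records, wMineralInitial, rhoM = 3.16,
                              rhoW = 1.00) {
  need <- c("sample_id", "timepoint_h", "w_wet_g")
  if (!all(need %in% colnames(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(records, records$sample_id), function(d) {
    d <- d[order(d$timepoint_h), , drop = FALSE]
    w0 <- if (length(wMineralInitial) > 1L)
      wMineralInitial[[as.character(d$sample_id[1L])]] else wMineralInitial
    ml <- mineralLost(d$w_wet_g - d$w_wet_g[1L], rhoM = rhoM, rhoW = rhoW)
    d$w_lost_g <- ml$wLost
    d$mineral_wt_percent <- mineralContentPercent(ml$wLost, w0)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
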