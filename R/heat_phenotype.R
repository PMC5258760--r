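#' Spikelet fertility summary for one line and condition
#'
#' Per plant, `SFP = FSP / TSP * 100` (percent of spikelets filled); the
#' summary is the mean and sample standard deviation over replicate plants.
#'
#' @param plants data.frame of plant records (`line_id`, `condition`,
#'   `plant`, `TSP`, `FSP`) for a single line and condition.
#' @return one-row data.frame: `line_id`, `condition`, `SFP_mean`, `SFP_sd`,
#'   `n_plants`.
#' @export
spikelet_fertility <- function(plants) {
  validate_plant_records(plants)
  if (length(unique(plants$line_id)) != 1 || length(unique(plants$condition)) != 1)
    stop("spikelet_fertility expects records of one line and one condition")
  sfp <- plants$FSP / plants$TSP * 100
  data.frame(line_id = plants$line_id[1], condition = plants$condition[1],
             SFP_mean = mean(sfp),
             SFP_sd = if (length(sfp) > 1) stats::sd(sfp) else NA_real_,
             n_plants = length(sfp), stringsAsFactors = FALSE)
}

#' Spikelet fertility for every line x condition group
#'
#' @param plants data.frame of plant records for any number of lines.
#' @return data.frame with one [spikelet_fertility()] row per group.
#' @export
fertility_by_line <- function(plants) {
  validate_plant_records(plants)
  groups <- unique(plants[, c("line_id", "condition")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- plants[plants$line_id == groups$line_id[i] &
                  plants$condition == groups$condition[i], , drop = FALSE]
    spikelet_fertility(sub)
  })
  do.call(rbind, res)
}

#' Heat tolerance index
#'
#' `HI = heat-stressed SFP / control SFP`; 1 means no fertility loss under
#' stress. The default is the ratio of group means, which reproduces
#' published summary arithmetic exactly (e.g. 55.8/66.4 -> 0.84); the
#' `"mean-of-ratios"` mode averages per-plant ratios instead and is meant
#' for uncertainty estimation on paired designs. `HI_sd` is delta-method
#' propagated from the two group standard errors when available.
#'
#' @param stress,control one-row fertility summaries
#'   (see [spikelet_fertility()]) for the same line.
#' @param method `"ratio-of-means"` (default) or `"mean-of-ratios"`; the
#'   latter requires `sfp_stress`/`sfp_control` per-plant vectors instead.
#' @param sfp_stress,sfp_control optional per-plant SFP vectors for the
#'   `"mean-of-ratios"` mode (paired by position).
#' @return one-row data.frame: `line_id`, `HI`, `HI_sd`.
#' @export
heat_tolerance_index <- function(stress, control,
                                 method = c("ratio-of-means", "mean-of-ratios"),
                                 sfp_stress = NULL, sfp_control = NULL) {
  method <- match.arg(method)
  if (!identical(stress$line_id, control$line_id))
    stop("stress and control summaries must describe the same line")
  if (control$SFP_mean <= 0)
    stop("undefined HI: control spikelet fertility is zero for line ", control$line_id)
  if (method == "mean-of-ratios") {
    if (is.null(sfp_stress) || is.null(sfp_control) ||
        length(sfp_stress) != length(sfp_control))
      stop("mean-of-ratios requires paired per-plant SFP vectors")
    r <- sfp_stress / sfp_control
    return(data.frame(line_id = stress$line_id, HI = mean(r),
                      HI_sd = if (length(r) > 1) stats::sd(r) else NA_real_,
                      stringsAsFactors = FALSE))
  }
  hi <- stress$SFP_mean / control$SFP_mean
  hi_sd <- NA_real_
  if (!is.na(stress$SFP_sd) && !is.na(control$SFP_sd)) {
    cv2 <- (stress$SFP_sd / stress$SFP_mean)^2 / stress$n_plants +
           (control$SFP_sd / control$SFP_mean)^2 / control$n_plants
    hi_sd <- hi * sqrt(cv2)
  }
  data.frame(line_id = stress$line_id, HI = hi, HI_sd = hi_sd,
             stringsAsFactors = FALSE)
}

#' Heat tolerance index for every line in a plant-record table
#'
#' @param plants data.frame of plant records covering both conditions.
#' @return data.frame with one row per line: `line_id`, `HI`, `HI_sd`.
#' @export
heat_tolerance <- function(plants) {
  fert <- fertility_by_line(plants)
  lines <- unique(fert$line_id)
  res <- lapply(lines, function(ln) {
    s <- fert[fert$line_id == ln & fert$condition == "heat", , drop = FALSE]
    ctl <- fert[fert$line_id == ln & fert$condition == "control", , drop = FALSE]
    if (nrow(s) != 1 || nrow(ctl) != 1)
      stop("line ", ln, " lacks a control/heat pair of fertility summaries")
    heat_tolerance_index(s, ctl)
  })
  do.call(rbind, res)
}
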