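# Beach-survey and habitat analytics for stranded jellyfish.

#' Allometric wet weight of a jellyfish from bell diameter
#'
#' Power law developed for the study region: `W = 0.0002 * D^2.8786`, with
#' `W` the total wet weight in grammes and `D` the bell diameter in mm.
#'
#' @param diameter_mm Bell diameter(s), mm; must be positive.
#' @return Wet weight(s), grammes.
#' @export
biomass <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    stop("bell diameter must be positive", call. = FALSE)
  }
  0.0002 * diameter_mm^2.8786
}

#' Abundance class of an eye-count observation
#'
#' Categories: 0 = no individuals, 1 = 1--10, 2 = 10--100, 3 = more than
#' 100. Boundary counts (10, 100) fall in the lower class. The
#' `large_aggregation` class is assigned only by explicit flag (events of
#' several hundred individuals), never inferred from the count.
#'
#' @param count Non-negative individual count(s).
#' @param large_aggregation Logical flag(s) for exceptional aggregation
#'   events.
#' @return Character vector of classes (`"0"`, `"1"`, `"2"`, `"3"`,
#'   `"large_aggregation"`).
#' @export
abundance_class <- function(count, large_aggregation = FALSE) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("count must be non-negative", call. = FALSE)
  }
  large_aggregation <- rep_len(large_aggregation, length(count))
  cls <- as.character(findInterval(count, c(1, 11, 101)))
  cls[large_aggregation] <- "large_aggregation"
  cls
}

#' Meteorological season of a date
#'
#' DJF = winter, MAM = spring, JJA = summer, SON = autumn.
#'
#' @param date `Date` vector (or parseable strings).
#' @return Factor with levels winter, spring, summer, autumn.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
  factor(s, levels = c("winter", "spring", "summer", "autumn"))
}

#' Read beach-survey records from CSV
#'
#' Expected columns: `date`, `site`, `coast` (sicily|calabria), `count`,
#' `diameters` (semicolon-separated bell diameters in mm, may be empty),
#' optional `reference_diameter` (mm) used to impute damaged specimens.
#'
#' @param path CSV file path.
#' @return Data frame of survey records with `diameters` as a list column.
#' @export
read_survey_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "site", "coast", "count", "diameters")
  if (!all(needed %in% names(raw))) {
    stop("survey CSV must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  raw$date <- as.Date(raw$date)
  raw$diameters <- lapply(raw$diameters, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    as.numeric(strsplit(trimws(s), ";")[[1]])
  })
  if (is.null(raw$reference_diameter)) raw$reference_diameter <- NA_real_
  bad <- vapply(raw$diameters, function(d) any(!is.finite(d) | d <= 0),
                logical(1))
  if (any(bad)) stop("diameters must all be positive", call. = FALSE)
  if (any(raw$count < 0)) stop("counts must be non-negative", call. = FALSE)
  n_meas <- vapply(raw$diameters, length, integer(1))
  if (any(n_meas > raw$count)) {
    stop("more measured diameters than counted individuals", call. = FALSE)
  }
  raw
}

.size_bins <- c(20, 30, 50, 70, 90)
.size_labels <- c("20-30", "30-50", "50-70", "70-90")

#' Seasonal size-class table of measured bell diameters
#'
#' Relative incidence (%) of diameters in the half-open bins
#' [20,30), [30,50), [50,70), [70,90) mm per meteorological season;
#' diameters outside 20--90 mm are reported in an `other` column rather
#' than dropped. Seasons with no measured specimens are `NA` (undefined),
#' not zero.
#'
#' @param records Survey records (as from [read_survey_csv()]).
#' @return Matrix seasons x size classes of percentages; rows sum to 100
#'   where defined.
#' @export
seasonal_size_table <- function(records) {
  n_meas <- vapply(records$diameters, length, integer(1))
  if (sum(n_meas) == 0) stop("no measured diameters", call. = FALSE)
  season <- rep(season_of(records$date), n_meas)
  d <- unlist(records$diameters)
  bin <- findInterval(d, .size_bins)  # 0 = <20, 5 = >=90
  lab <- c("other", .size_labels, "other")[bin + 1]
  lab <- factor(lab, levels = c(.size_labels, "other"))
  tab <- table(season, lab)
  out <- matrix(NA_real_, nrow = nlevels(season), ncol = ncol(tab),
                dimnames = dimnames(tab))
  totals <- rowSums(tab)
  defined <- totals > 0
  out[defined, ] <- 100 * tab[defined, , drop = FALSE] / totals[defined]
  out
}

#' Seasonal cumulative stranded biomass per coast
#'
#' Sums per-specimen wet weights by coast and meteorological season.
#' Unmeasured individuals (count minus measured diameters) are imputed at
#' the record's `reference_diameter` when provided, mirroring the use of a
#' reference specimen for damaged strandings; with no reference they are
#' left out of the biomass (measured specimens only).
#'
#' @param records Survey records (as from [read_survey_csv()]).
#' @return Data frame coast x season with `biomass_g` and `pct_of_total`
#'   (percentages over both coasts sum to 100).
#' @export
seasonal_biomass <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(coast = character(0), season = character(0),
                      biomass_g = numeric(0), pct_of_total = numeric(0)))
  }
  per_record <- vapply(seq_len(nrow(records)), function(i) {
    d <- records$diameters[[i]]
    w <- if (length(d)) sum(biomass(d)) else 0
    miss <- records$count[i] - length(d)
    ref <- records$reference_diameter[i]
    if (miss > 0 && !is.na(ref)) w <- w + miss * biomass(ref)
    w
  }, numeric(1))
  season <- season_of(records$date)
  agg <- stats::aggregate(per_record,
                          by = list(coast = records$coast, season = season),
                          FUN = sum, drop = FALSE)
  names(agg)[3] <- "biomass_g"
  agg$biomass_g[is.na(agg$biomass_g)] <- 0
  total <- sum(agg$biomass_g)
  agg$pct_of_total <- if (total > 0) 100 * agg$biomass_g / total else 0
  agg
}

#' Observed vs modeled coast stranding ratio
#'
#' Calabria-to-Sicily ratios of summer stranding totals, truncated to one
#' decimal to mirror the precision of field estimates.
#'
#' @param observed Named or ordered numeric `c(calabria, sicily)` observed
#'   counts.
#' @param modeled Optional modeled stranding totals, same convention.
#' @return List with `observed_ratio` and (if supplied) `modeled_ratio`.
#' @export
stranding_rate_comparison <- function(observed, modeled = NULL) {
  ratio1 <- function(v) {
    v <- unname(v)
    if (length(v) != 2 || v[2] <= 0) {
      stop("need positive (calabria, sicily) totals", call. = FALSE)
    }
    trunc(10 * v[1] / v[2]) / 10
  }
  out <- list(observed_ratio = ratio1(observed))
  if (!is.null(modeled)) out$modeled_ratio <- ratio1(modeled)
  out
}

#' Current-speed distribution and tidal-phase means
#'
#' @param records Data frame with columns `speed` (m/s, 2-D modulus) and
#'   optionally `along_component` (signed along-channel speed, positive on
#'   the flood/northward phase).
#' @param threshold Slack threshold, m/s (default 0.05).
#' @param breaks Histogram breaks passed to [hist()].
#' @return List: `fraction_below` (share of records below the threshold),
#'   `phase_means` (mean speed on ebb/flood, `NA` without a signed
#'   component), `histogram`.
#' @export
speed_distribution <- function(records, threshold = 0.05, breaks = "Sturges") {
  stopifnot(nrow(records) >= 1, all(records$speed >= 0))
  frac <- mean(records$speed < threshold)
  phase_means <- c(ebb = NA_real_, flood = NA_real_)
  if (!is.null(records$along_component)) {
    phase <- ifelse(records$along_component >= 0, "flood", "ebb")
    m <- tapply(records$speed, phase, mean)
    phase_means[names(m)] <- m
  }
  h <- graphics::hist(records$speed, breaks = breaks, plot = FALSE)
  list(fraction_below = frac, phase_means = phase_means, histogram = h)
}

#' Upwelling depth from a density-anomaly profile
#'
#' Shallowest depth at which sigma-t reaches the threshold marking
#' upwelled deep water, linearly interpolated between samples. If the
#' surface sample already reaches the threshold the dense water occupies
#' the whole column and `surface_reached` is `TRUE`.
#'
#' @param depths Depths, m, strictly increasing from the surface.
#' @param sigma_t Density anomaly values, kg/m^3.
#' @param sigma_threshold Threshold (default 28.5).
#' @return List with `depth` (m, `NA` if never reached) and
#'   `surface_reached`.
#' @export
upwelling_depth <- function(depths, sigma_t, sigma_threshold = 28.5) {
  if (length(depths) == 0 || length(depths) != length(sigma_t)) {
    stop("profile must be non-empty with matching lengths", call. = FALSE)
  }
  if (any(diff(depths) <= 0) || any(depths < 0)) {
    stop("depths must be non-negative and strictly increasing", call. = FALSE)
  }
  if (sigma_t[1] >= sigma_threshold) {
    return(list(depth = depths[1], surface_reached = TRUE))
  }
  above <- which(sigma_t >= sigma_threshold)
  if (length(above) == 0) {
    return(list(depth = NA_real_, surface_reached = FALSE))
  }
  i <- above[1]
  d <- depths[i - 1] + (depths[i] - depths[i - 1]) *
    (sigma_threshold - sigma_t[i - 1]) / (sigma_t[i] - sigma_t[i - 1])
  list(depth = d, surface_reached = FALSE)
}
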