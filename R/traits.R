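#' Mean intestinal diameter from interval measurements
#'
#' The intestinal diameter of a specimen is the arithmetic mean of external
#' diameter measurements taken at equal intervals along the unraveled
#' intestine (ten by default).
#'
#' @param diameters Numeric vector of strictly positive diameters (cm).
#' @param n_expected Required number of measurements (default 10).
#' @param allow_partial If `TRUE`, accept any count of at least 3
#'   measurements (logged); otherwise the count must equal `n_expected`.
#' @return Mean diameter in cm.
#' @export
mean_diameter <- function(diameters, n_expected = 10L, allow_partial = FALSE) {
  diameters <- as.numeric(diameters)
  if (anyNA(diameters) || any(diameters <= 0)) {
    stop("diameters must all be strictly positive and non-missing")
  }
  if (length(diameters) != n_expected) {
    if (!allow_partial) {
      stop(sprintf("expected %d diameter measurements, got %d",
                   n_expected, length(diameters)))
    }
    if (length(diameters) < 3L) {
      stop("allow_partial requires at least 3 diameter measurements")
    }
    gs_log("traits", "partial diameter series accepted (%d of %d measurements)",
           length(diameters), n_expected)
  }
  mean(diameters)
}

#' External intestinal surface area (cylinder approximation)
#'
#' Approximates the intestine as a cylinder of length `IL` and mean outer
#' radius `ID / 2`, giving a surface area of `2 * pi * r * IL = pi * ID * IL`.
#' This external area is a proxy for mucosal surface area; it does not
#' account for mucosal folding or sacculation.
#'
#' @param ID Mean outer intestinal diameter (cm).
#' @param IL Intestinal length (cm).
#' @return Surface area in cm^2.
#' @examples
#' surface_area(ID = 0.5, IL = 20) # pi * 0.5 * 20
#' @export
surface_area <- function(ID, IL) {
  if (any(!is.finite(ID)) || any(!is.finite(IL)) || any(ID <= 0) || any(IL <= 0)) {
    stop("ID and IL must be strictly positive")
  }
  pi * ID * IL
}

#' Build a specimen table from raw measurements
#'
#' Validates a raw specimen table (one row per fish) and derives the mean
#' diameter and external surface area columns.
#'
#' @param df Data frame with columns `species`, `sl_cm`, `il_cm` and
#'   diameter columns `d1_cm` ... `d10_cm` (count configurable).
#' @param n_diameters Number of diameter columns expected (default 10).
#' @return The validated data frame with derived columns `id_cm` (mean
#'   diameter) and `is_cm2` (surface area).
#' @export
as_specimens <- function(df, n_diameters = 10L) {
  df <- as.data.frame(df)
  dcols <- paste0("d", seq_len(n_diameters), "_cm")
  need <- c("species", "sl_cm", "il_cm", dcols)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("specimen table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$species <- gsub(" ", "_", as.character(df$species), fixed = TRUE)
  num <- c("sl_cm", "il_cm", dcols)
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  bad <- !stats::complete.cases(df[num]) |
    Reduce(`|`, lapply(df[num], function(x) x <= 0))
  if (any(bad)) {
    stop("specimen rows with missing or nonpositive measurements: ",
         paste(which(bad), collapse = ", "))
  }
  D <- as.matrix(df[dcols])
  df$id_cm <- rowMeans(D)
  df$is_cm2 <- surface_area(df$id_cm, df$il_cm)
  df
}

#' Read a specimen CSV
#'
#' @param path CSV file with the columns documented in [as_specimens()].
#' @param n_diameters Number of diameter columns expected.
#' @return Validated specimen data frame with derived trait columns.
#' @export
read_specimens <- function(path, n_diameters = 10L) {
  as_specimens(utils::read.csv(path, stringsAsFactors = FALSE), n_diameters)
}

#' Validate a species metadata table
#'
#' @param df Data frame with columns `species`, `tl` (trophic level),
#'   `el` (elongation: standard length / max body depth), `stomach` and
#'   `durophagy` (0/1 or true/false), and `max_size_cm` (reported maximum
#'   body size, used by the reliability filter).
#' @return Validated data frame with `stomach`/`durophagy` coerced to 0/1.
#' @export
as_species_metadata <- function(df) {
  df <- as.data.frame(df)
  need <- c("species", "tl", "el", "stomach", "durophagy", "max_size_cm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("metadata table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$species <- gsub(" ", "_", as.character(df$species), fixed = TRUE)
  if (anyDuplicated(df$species)) {
    stop("duplicate species in metadata: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  to01 <- function(x) {
    if (is.logical(x)) return(as.integer(x))
    if (is.character(x)) x <- tolower(trimws(x))
    out <- ifelse(x %in% c("1", "true", "yes", 1, TRUE), 1L,
                  ifelse(x %in% c("0", "false", "no", 0, FALSE), 0L, NA_integer_))
    if (anyNA(out)) stop("boolean column has values outside {0,1,true,false}")
    out
  }
  df$stomach <- to01(df$stomach)
  df$durophagy <- to01(df$durophagy)
  df$tl <- as.numeric(df$tl)
  df$el <- as.numeric(df$el)
  df$max_size_cm <- as.numeric(df$max_size_cm)
  if (any(!is.finite(df$tl)) || any(df$tl < 1)) stop("trophic level must be >= 1")
  if (any(!is.finite(df$el)) || any(df$el <= 0)) stop("elongation must be > 0")
  if (any(!is.finite(df$max_size_cm)) || any(df$max_size_cm <= 0)) {
    stop("max_size_cm must be > 0")
  }
  df
}

#' Read a species metadata CSV
#' @param path CSV file with the columns documented in [as_species_metadata()].
#' @return Validated metadata data frame.
#' @export
read_species_metadata <- function(path) {
  as_species_metadata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Fill missing trophic levels by group means
#'
#' Optional helper mirroring common practice when a species-level value is
#' unavailable: impute the mean of congeners (or family members). Every
#' imputation is logged.
#'
#' @param metadata Metadata data frame with possibly missing `tl` values.
#' @param group Character vector (same length as rows) giving the genus or
#'   family of each species.
#' @return Metadata with `tl` imputed where possible.
#' @export
impute_tl_by_group <- function(metadata, group) {
  stopifnot(length(group) == nrow(metadata))
  miss <- which(is.na(metadata$tl))
  for (i in miss) {
    peers <- metadata$tl[group == group[i]]
    m <- mean(peers, na.rm = TRUE)
    if (is.finite(m)) {
      gs_log("traits", "imputed tl for %s from group %s mean (%.3f)",
             metadata$species[i], group[i], m)
      metadata$tl[i] <- m
    }
  }
  metadata
}

#' Assemble the observation-level modeling table
#'
#' Joins specimens with species metadata and applies the natural-log
#' transforms: the response (one of intestinal length, diameter, or surface
#' area), standard length, and elongation are all log-transformed.
#'
#' @param specimens Specimen table from [as_specimens()].
#' @param metadata Metadata table from [as_species_metadata()].
#' @param response One of `"length"`, `"diameter"`, `"surface"`.
#' @return Data frame with one row per specimen: `species`, `ln_y`,
#'   `ln_sl`, `tl`, `ln_el`, `stomach`, `durophagy`, plus the raw `sl_cm`.
#' @export
assemble_model_table <- function(specimens, metadata,
                                 response = c("length", "diameter", "surface")) {
  response <- match.arg(response)
  orphans <- setdiff(unique(specimens$species), metadata$species)
  if (length(orphans) > 0L) {
    stop("species without metadata: ", paste(sort(orphans), collapse = ", "))
  }
  y <- switch(response,
              length   = specimens$il_cm,
              diameter = specimens$id_cm,
              surface  = specimens$is_cm2)
  idx <- match(specimens$species, metadata$species)
  out <- data.frame(
    species   = specimens$species,
    ln_y      = log(y),
    ln_sl     = log(specimens$sl_cm),
    sl_cm     = specimens$sl_cm,
    tl        = metadata$tl[idx],
    ln_el     = log(metadata$el[idx]),
    stomach   = metadata$stomach[idx],
    durophagy = metadata$durophagy[idx],
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$ln_y)) || any(!is.finite(out$ln_sl))) {
    stop("non-finite values after log transform")
  }
  attr(out, "response") <- response
  out
}

#' Split body size into between- and within-species components
#'
#' Adds the species mean of log standard length (`ln_sl_bar`, the
#' interspecific size axis) and the within-species centered deviation
#' (`ln_sl_dev = ln_sl - ln_sl_bar`, the intraspecific axis, which carries
#' the species-level random slope). Deviations sum to zero within species
#' by construction.
#'
#' @param table Modeling table from [assemble_model_table()].
#' @return The table with `ln_sl_bar` and `ln_sl_dev` columns added.
#' @export
decompose_size <- function(table) {
  stopifnot("ln_sl" %in% names(table), "species" %in% names(table))
  bar <- tapply(table$ln_sl, table$species, mean)
  table$ln_sl_bar <- as.numeric(bar[table$species])
  table$ln_sl_dev <- table$ln_sl - table$ln_sl_bar
  table
}

#' Standardize the continuous predictors
#'
#' Z-scores the continuous covariates (species-mean log size, trophic
#' level, log elongation) across observations, so the intercept is the
#' trait at the average body size, trophic level, and elongation of the
#' data, and slopes are comparable. The within-species size deviation is
#' centered by construction and is deliberately not re-scaled: its slope
#' stays interpretable as a log-log allometric exponent.
#'
#' @param table Modeling table from [decompose_size()].
#' @param covariates Columns to standardize.
#' @return List with `table` (standardized columns added as `z_<name>`) and
#'   `record`, a data.frame of per-covariate centers and scales used to map
#'   new values (e.g. a prediction size of 15 cm) into model space.
#' @export
standardize <- function(table, covariates = c("ln_sl_bar", "tl", "ln_el")) {
  record <- data.frame(variable = covariates, center = NA_real_, scale = NA_real_,
                       stringsAsFactors = FALSE)
  for (k in seq_along(covariates)) {
    v <- covariates[k]
    x <- table[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    ctr <- mean(x)
    scl <- stats::sd(x)
    if (!is.finite(scl) || scl <= 0) stop("zero variance in covariate: ", v)
    record$center[k] <- ctr
    record$scale[k] <- scl
    table[[paste0("z_", v)]] <- (x - ctr) / scl
  }
  list(table = table, record = record)
}

#' Apply a stored standardization to new values
#'
#' @param record Standardization record from [standardize()].
#' @param variable Covariate name.
#' @param x Raw values on the covariate's own (possibly log) scale.
#' @return Standardized values.
#' @export
apply_standardization <- function(record, variable, x) {
  i <- match(variable, record$variable)
  if (is.na(i)) stop("no standardization stored for: ", variable)
  (x - record$center[i]) / record$scale[i]
}
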