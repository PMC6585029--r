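#' Load the environmental endpoint-burden fixture
#'
#' Reads the transcribed per-scenario environmental Human Health burden
#' table (DALYs per pathway element and resource type, three scenario
#' blocks) shipped with the package. Cells printed as non-determined are
#' stored as zero; the treatment-interruption block has no supply-chain
#' elements.
#'
#' @param path CSV path; default the shipped fixture.
#' @return An object of class `env_burden_table` (long data frame with
#'   columns `scenario`, `element`, `resource`, `daly`).
#' @export
load_env_burden_table <- function(path = system.file("extdata",
                                                     "env_burden_endpoint_dalys.csv",
                                                     package = "netdaly")) {
  if (!nzchar(path) || !file.exists(path))
    stop("burden table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "element", "resource", "daly")
  if (!all(need %in% names(df)) || !nrow(df))
    stop("malformed burden table (need columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  if (any(!is.finite(df$daly)))
    stop("non-numeric burden cell at line ",
         which(!is.finite(df$daly))[1] + 1, call. = FALSE)
  structure(df, class = c("env_burden_table", "data.frame"))
}

#' Load the published consumption-profile counts
#'
#' Element totals (syringes, visits, bed days) per scenario for 1000
#' patients over one year, as printed alongside the burden table.
#'
#' @param path CSV path; default the shipped fixture.
#' @return Data frame with columns `scenario`, `element`, `count`.
#' @export
load_consumption_counts <- function(path = system.file("extdata",
                                                       "consumption_profile_counts.csv",
                                                       package = "netdaly")) {
  if (!nzchar(path) || !file.exists(path))
    stop("consumption counts not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("scenario", "element", "count") %in% names(df)) || !nrow(df))
    stop("malformed consumption-count table", call. = FALSE)
  df
}

supply_elements <- function() c("api", "drug_production", "packaging",
                                "distribution_supply", "end_of_life")
care_elements <- function() c("gp_visits", "psychiatrist_visits",
                              "ambulatory_visits", "general_bed_days",
                              "psychiatric_bed_days")

#' One scenario's burden block as a resource x element matrix
#'
#' @param table An [load_env_burden_table()] table.
#' @param scenario Scenario id.
#' @return Numeric matrix (resources x elements).
#' @export
scenario_block <- function(table, scenario) {
  stopifnot(inherits(table, "env_burden_table"))
  b <- table[table$scenario == scenario, ]
  if (!nrow(b)) stop("unknown scenario: ", scenario, call. = FALSE)
  stats::xtabs(daly ~ resource + element, data = b) |> unclass()
}

#' Derive per-unit endpoint factors from the burden blocks
#'
#' Divides burden cells by the published element counts to obtain DALYs
#' per unit of care. Care-provider factors (per visit, per bed day) come
#' from the treatment-interruption block, which has the largest counts;
#' supply-chain factors are expressed per syringe — from the PP1M block
#' divided by its 805 syringes, and from the PP3M block either blended
#' over all its syringes (default; reproduces the block sum exactly) or
#' attributed by solving the two-scenario linear system
#' (`attribution = "solve"`), which assigns the PP1M per-syringe factor to
#' the re-initiation syringes and the remainder to the three-monthly
#' syringes.
#'
#' @param table An [load_env_burden_table()] table.
#' @param counts A [load_consumption_counts()] data frame.
#' @param attribution `"blended"` or `"solve"` for the PP3M supply chain.
#' @return An object of class `env_factor_table`: list with `care`
#'   (resource x element matrix, DALY per unit) and `supply` (list of
#'   per-syringe resource x element matrices keyed by scenario).
#' @export
derive_unit_factors <- function(table, counts = load_consumption_counts(),
                                attribution = c("blended", "solve")) {
  attribution <- match.arg(attribution)
  cnt <- function(scen, el) {
    v <- counts$count[counts$scenario == scen & counts$element == el]
    if (!length(v)) stop("missing count for ", scen, "/", el, call. = FALSE)
    v
  }
  ti <- scenario_block(table, "ti")
  care <- ti[, care_elements(), drop = FALSE]
  care_counts <- vapply(care_elements(), function(e) cnt("ti", e), numeric(1))
  if (any(care_counts == 0 & colSums(abs(care)) > 0))
    stop("zero count with nonzero burden in care elements", call. = FALSE)
  care <- sweep(care, 2, care_counts, "/")

  pp1m <- scenario_block(table, "pp1m")[, supply_elements(), drop = FALSE]
  n1 <- cnt("pp1m", "syringe_1m")
  if (n1 <= 0) stop("zero syringe count with nonzero supply burden", call. = FALSE)
  f1 <- pp1m / n1

  pp3m <- scenario_block(table, "pp3m")[, supply_elements(), drop = FALSE]
  n3_1m <- cnt("pp3m", "syringe_1m")
  n3_3m <- cnt("pp3m", "syringe_3m")
  f3 <- switch(attribution,
    blended = pp3m / (n3_1m + n3_3m),
    solve = (pp3m - n3_1m * f1) / n3_3m)
  structure(list(care = care,
                 supply = list(pp1m = f1, pp3m = f3),
                 attribution = attribution),
            class = "env_factor_table")
}

#' Environmental burden of a consumption profile
#'
#' Multiplies each element count by its per-unit factor, producing the
#' resource x element burden breakdown, element and resource totals, and
#' the grand total (the scenario's environmental DALYs). Strictly linear
#' in the profile; energy-recovery credits keep some cells negative.
#'
#' @param profile A `consumption_profile` (or named numeric vector of
#'   element counts).
#' @param factors An [derive_unit_factors()] table.
#' @param supply Which per-syringe supply-chain factor applies:
#'   `"pp1m"`, `"pp3m"` (blended over both syringe types), or `"none"`
#'   (treatment interruption). Default follows the profile's scenario.
#' @return An object of class `burden_breakdown`.
#' @export
compute_env_burden <- function(profile, factors, supply = NULL) {
  stopifnot(inherits(factors, "env_factor_table"))
  if (is.null(supply)) {
    supply <- attr(profile, "scenario")
    if (is.null(supply)) stop("supply attribution not given and profile has no scenario",
                              call. = FALSE)
    if (supply == "ti") supply <- "none"
  }
  supply <- match.arg(supply, c("pp1m", "pp3m", "none"))
  p <- unclass(profile)
  missing_el <- setdiff(care_elements(), names(p))
  if (length(missing_el))
    stop("profile is missing elements: ", paste(missing_el, collapse = ", "),
         call. = FALSE)
  cells <- sweep(factors$care, 2, p[care_elements()], "*")
  if (supply != "none") {
    n_syr <- sum(p[c("syringe_1m", "syringe_3m")], na.rm = TRUE)
    if (supply == "pp1m") n_syr <- p[["syringe_1m"]]
    cells <- cbind(factors$supply[[supply]] * n_syr, cells)
  }
  element_totals <- colSums(cells)
  resource_totals <- rowSums(cells)
  structure(list(cells = cells,
                 element_totals = element_totals,
                 resource_totals = resource_totals,
                 total = sum(cells),
                 supply = supply),
            class = "burden_breakdown")
}

#' Contribution shares of a burden breakdown
#'
#' Percentage of the grand total per element (with the five supply-chain
#' phases also aggregated into one `supply_chain` share) and per resource
#' type.
#'
#' @param breakdown A [compute_env_burden()] breakdown, or a raw
#'   resource x element matrix (e.g. a [scenario_block()]).
#' @return List with `element` (named percentages), `supply_chain`
#'   (aggregate percentage), and `resource`.
#' @export
contribution_shares <- function(breakdown) {
  cells <- if (inherits(breakdown, "burden_breakdown")) breakdown$cells else breakdown
  gt <- sum(cells)
  if (gt == 0) stop("shares undefined: grand total is zero", call. = FALSE)
  el <- 100 * colSums(cells) / gt
  sc <- sum(el[intersect(supply_elements(), names(el))])
  list(element = el, supply_chain = sc, resource = 100 * rowSums(cells) / gt)
}

#' Resource-type shares within one element
#'
#' Shares of the resource types making up one element's burden. Hospital
#' resource profiles are conventionally reported on on-site resource use,
#' so patient transport is excluded by default.
#'
#' @param breakdown A `burden_breakdown` or resource x element matrix.
#' @param element Element name.
#' @param exclude_transport Drop the transport row before computing shares.
#' @return Named percentage vector over resource types.
#' @export
resource_shares <- function(breakdown, element, exclude_transport = TRUE) {
  cells <- if (inherits(breakdown, "burden_breakdown")) breakdown$cells else breakdown
  v <- cells[, element]
  if (exclude_transport) v <- v[setdiff(names(v), "transport")]
  if (sum(v) == 0) stop("shares undefined: element burden is zero", call. = FALSE)
  100 * v / sum(v)
}

#' Drug mass emitted to freshwater at end of life
#'
#' Administered dose minus the fraction metabolized in the patient and the
#' fraction removed in the wastewater treatment plant:
#' `dose * (1 - 0.41) * (1 - 0.64)` with the default parameters. Also
#' reports the corresponding paliperidone palmitate mass (1 mg-eq =
#' 1.56 mg).
#'
#' @param dose_mg_eq Administered dose in mg-equivalents (>= 0).
#' @param params An [make_eol_parameters()] set.
#' @return List with `emitted_mg_eq` and `emitted_mg_palmitate`.
#' @export
eol_emitted_mass <- function(dose_mg_eq, params = make_eol_parameters()) {
  stopifnot(inherits(params, "eol_parameters"))
  if (any(dose_mg_eq < 0)) stop("dose must be >= 0", call. = FALSE)
  em <- dose_mg_eq * (1 - params$fraction_metabolized) *
    (1 - params$fraction_wwtp_removed)
  list(emitted_mg_eq = em, emitted_mg_palmitate = em * params$mg_per_mg_eq)
}

#' @export
print.burden_breakdown <- function(x, ...) {
  cat("<burden_breakdown> total ", signif(x$total, 4), " environmental DALYs",
      " (supply chain: ", x$supply, ")\n", sep = "")
  print(round(sort(x$element_totals, decreasing = TRUE), 4))
  invisible(x)
}
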