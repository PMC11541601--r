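# Published 2PL parameters for the nine screening rules, used as the
# simulation truth. The total-sample estimates come from a national
# mental-health survey (n = 15,893); the group-specific sets are the
# reference/focal estimates from the corresponding DIF analyses, where a
# focal entry exists only for items that displayed DIF (otherwise the
# focal group shares the reference parameters).

.SCREEN_ITEMS <- c("SC20", "SC21", "SC22", "SC23", "SC24", "SC25",
                   "SC26", "SC29", "SC30")

.REFERENCE_A <- c(1.791, 3.518, 4.641, 3.799, 1.752, 2.069, 2.280, 1.822, 2.048)
.REFERENCE_B <- c(0.102, 0.248, 0.206, 0.381, 1.849, 0.770, 0.092, 1.126, 1.526)

# Per grouping variable: reference-group (a, b) and, for DIF items only,
# focal-group (a, b). NA marks "no DIF: focal fixed to reference".
.GROUP_TRUTH <- list(
  sex = list(
    reference = "Female", focal = "Male",
    refA = c(1.844, 3.382, 4.980, 3.948, 1.866, 1.981, 2.285, 1.743, 1.996),
    refB = c(-0.084, 0.145, 0.128, 0.308, 1.827, 0.690, -0.060, 1.061, 1.386),
    focA = c(1.561, NA, 3.965, 3.346, 1.571, NA, 2.051, NA, 1.899),
    focB = c(0.102, NA, 0.071, 0.257, 1.745, NA, 0.040, NA, 1.627)),
  age = list(
    reference = "Younger", focal = "Older",
    refA = c(1.856, 3.869, 4.847, 3.941, 1.582, 2.175, 2.327, 1.809, 2.102),
    refB = c(-0.041, 0.154, 0.057, 0.227, 1.665, 0.479, -0.124, 0.850, 1.341),
    focA = c(NA, 3.657, NA, NA, 2.020, 2.047, 2.360, 1.887, NA),
    focB = c(NA, 0.054, NA, NA, 1.563, 0.735, 0.003, 1.060, NA)),
  employment = list(
    reference = "Employed/NILF", focal = "Unemployed",
    refA = c(1.783, 3.550, 4.620, 3.781, 1.745, 2.057, 2.272, 1.815, 2.037),
    refB = c(0.111, 0.254, 0.215, 0.391, 1.867, 0.783, 0.101, 1.140, 1.543),
    focA = c(NA, 2.407, NA, NA, NA, NA, NA, NA, NA),
    focB = c(NA, 0.421, NA, NA, NA, NA, NA, NA, NA)),
  location = list(
    reference = "Regional/Remote", focal = "Metro",
    refA = c(1.781, 3.498, 4.615, 3.778, 1.742, 2.057, 2.266, 1.881, 2.036),
    refB = c(0.106, 0.252, 0.210, 0.386, 1.863, 0.777, 0.096, 1.198, 1.538),
    focA = c(NA, NA, NA, NA, NA, NA, NA, 1.793, NA),
    focB = c(NA, NA, NA, NA, NA, NA, NA, 1.116, NA)),
  substance = list(
    reference = "No substance", focal = "Substance",
    refA = c(1.771, 3.495, 4.575, 3.804, 1.730, 2.047, 2.254, 1.801, 2.020),
    refB = c(0.130, 0.273, 0.234, 0.410, 1.914, 0.805, 0.120, 1.166, 1.573),
    focA = c(NA, 3.533, NA, 2.573, 1.371, NA, NA, NA, NA),
    focB = c(NA, 0.420, NA, 0.394, 1.779, NA, NA, NA, NA)))

#' Total-sample reference item parameters
#'
#' The published total-sample 2PL estimates for the nine screening rules,
#' the default truth of the synthetic-data generator.
#'
#' @return An [ItemParameters-class] for SC20..SC30.
#' @examples
#' round(itemLoadings(referenceItemParameters()), 3)
#' @export
referenceItemParameters <- function()
  itemParameters(.SCREEN_ITEMS, .REFERENCE_A, .REFERENCE_B)

#' Group-specific item parameters from the published DIF analyses
#'
#' Reference and focal truth for one grouping variable. Items without DIF
#' share the reference parameters in the focal set, mirroring the anchored
#' cells of the published group-specific table.
#'
#' @param grouping one of "sex", "age", "employment", "location",
#'   "substance".
#' @return List with `reference` and `focal` ([ItemParameters-class]),
#'   `labels` (reference and focal group names) and `difItems` (items whose
#'   focal parameters differ).
#' @examples
#' groupItemParameters("sex")$difItems
#' @export
groupItemParameters <- function(grouping = c("sex", "age", "employment",
                                             "location", "substance")) {
  grouping <- match.arg(grouping)
  g <- .GROUP_TRUTH[[grouping]]
  focA <- ifelse(is.na(g$focA), g$refA, g$focA)
  focB <- ifelse(is.na(g$focB), g$refB, g$focB)
  list(reference = itemParameters(.SCREEN_ITEMS, g$refA, g$refB),
       focal = itemParameters(.SCREEN_ITEMS, focA, focB),
       labels = c(reference = g$reference, focal = g$focal),
       difItems = .SCREEN_ITEMS[!is.na(g$focA) | !is.na(g$focB)])
}
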