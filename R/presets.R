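#' Life-course cohort preset generator
#'
#' A six-block synthetic cohort emulating the structure of a birth-cohort
#' life-course study: a forced binary covariate (sex) adjusting every
#' regression, prenatal maternal exposures (continuous, binary and one
#' three-level categorical), birth size, infancy and childhood growth
#' parameters (adiposity peak/rebound), adolescent BMI and lifestyle,
#' adult anthropometric and metabolic traits, and a distal middle-age BMI
#' outcome. Twenty-nine sparse forward-only true edges carry standardised
#' effects of magnitude 0.30-0.50; residual variances are set so every
#' endogenous variable has (near) unit total variance. The optional
#' missingness mechanism is MAR driven by sex, with per-variable rates of
#' 10-15% on seven variables.
#'
#' The preset makes no attempt to mimic the marginal distributions or
#' effect sizes of any real cohort; it provides known ground truth at a
#' realistic structural scale.
#'
#' @param n default number of subjects.
#' @param missingness include the MAR mechanism (`TRUE`) or produce a
#'   complete-data spec (`FALSE`).
#' @return a `blsem_genspec`.
#' @examples
#' spec <- nfbc_like_spec(n = 500)
#' sim <- simulate_cohort(spec, seed = 42)
#' dim(sim$data)
#' @export
nfbc_like_spec <- function(n = 4000, missingness = TRUE) {
  bs <- nfbc_like_blocks()

  edges <- data.frame(
    from = c("matBMI", "gestAge", "matSmoke", "placWt",
             "bw", "matBMI",
             "bw",
             "bmiAP", "matBMI", "matSmoke",
             "bmiAP", "matSEP",
             "bmiAR", "ageAR", "matBMI", "smoke14",
             "bmi14", "matBMI", "pa31", "alc31",
             "bmi14",
             "bmi14", "matBMI",
             "bmi14", "alc31",
             "bmi31", "bmi14", "matSmoke", "sep46",
             "sex", "sex", "sex"),
    to = c("bw", "bw", "bw", "bw",
           "bmiAP", "bmiAP",
           "ageAP",
           "bmiAR", "bmiAR", "bmiAR",
           "ageAR", "ageAR",
           "bmi14", "bmi14", "bmi14", "bmi14",
           "bmi31", "bmi31", "bmi31", "bmi31",
           "insulin31",
           "trig31", "trig31",
           "bpf31", "bpf31",
           "bmi46", "bmi46", "bmi46", "bmi46",
           "bw", "bmiAP", "bmi46"),
    beta = c(0.30, 0.45, -0.35, 0.35,
             0.40, 0.30,
             0.30,
             0.45, 0.30, 0.30,
             -0.35, 0.30,
             0.45, -0.40, 0.30, -0.30,
             0.50, 0.30, -0.30, 0.30,
             0.40,
             0.35, 0.30,
             0.35, 0.30,
             0.50, 0.30, 0.30, -0.30,
             0.30, 0.40, 0.20),
    stringsAsFactors = FALSE)

  src <- c("sex", "matBMI", "matAge", "matSEP", "matSmoke", "parity",
           "gestAge", "placWt", "town", "smoke14", "alc31", "pa31",
           "sep46")
  R <- diag(length(src)); dimnames(R) <- list(src, src)
  R["matBMI", "matSEP"] <- R["matSEP", "matBMI"] <- 0.20
  R["matSmoke", "matSEP"] <- R["matSEP", "matSmoke"] <- 0.25
  R["matSmoke", "smoke14"] <- R["smoke14", "matSmoke"] <- 0.30
  R["matBMI", "placWt"] <- R["placWt", "matBMI"] <- 0.20
  R["alc31", "pa31"] <- R["pa31", "alc31"] <- -0.20

  ms <- if (missingness) list(
    type = "mar", driver = "sex", logodds = 0.5,
    targets = list(matSEP = 0.10, placWt = 0.15, bmiAP = 0.15,
                   ageAR = 0.15, bmi14 = 0.10, insulin31 = 0.15,
                   smoke14 = 0.10))
  else NULL

  generator_spec(
    bs, edges, exo_cor = R,
    prevalence = list(sex = 0.5, matSmoke = 0.30, smoke14 = 0.25,
                      town = c(0.5, 0.3, 0.2)),
    missingness = ms, n = n)
}

#' Block structure of the life-course preset
#'
#' @return a `blsem_blocks` with 6 blocks, 24 variables (25 model
#'   columns) and 11 endogenous responses.
#' @export
nfbc_like_blocks <- function() {
  block_structure(
    blocks = list(
      list(name = "prenatal_birth",
           endogenous = "bw",
           exogenous = c("sex", "matBMI", "matAge", "matSEP", "matSmoke",
                         "parity", "gestAge", "placWt", "town")),
      list(name = "infancy",
           endogenous = c("bmiAP", "ageAP"), exogenous = character()),
      list(name = "childhood",
           endogenous = c("bmiAR", "ageAR"), exogenous = character()),
      list(name = "adolescence",
           endogenous = "bmi14", exogenous = "smoke14"),
      list(name = "adulthood31",
           endogenous = c("bmi31", "insulin31", "trig31", "bpf31"),
           exogenous = c("alc31", "pa31")),
      list(name = "midlife46",
           endogenous = "bmi46", exogenous = "sep46")
    ),
    variables = list(
      sex = list(type = "binary", forced = TRUE),
      matBMI = list(type = "continuous"),
      matAge = list(type = "continuous"),
      matSEP = list(type = "continuous"),
      matSmoke = list(type = "binary"),
      parity = list(type = "continuous"),
      gestAge = list(type = "continuous"),
      placWt = list(type = "continuous"),
      town = list(type = "categorical",
                  levels = c("city", "town", "village")),
      bw = list(type = "continuous"),
      bmiAP = list(type = "continuous"),
      ageAP = list(type = "continuous"),
      bmiAR = list(type = "continuous"),
      ageAR = list(type = "continuous"),
      bmi14 = list(type = "continuous"),
      smoke14 = list(type = "binary"),
      bmi31 = list(type = "continuous"),
      insulin31 = list(type = "continuous"),
      trig31 = list(type = "continuous"),
      bpf31 = list(type = "continuous"),
      alc31 = list(type = "continuous"),
      pa31 = list(type = "continuous"),
      sep46 = list(type = "continuous"),
      bmi46 = list(type = "continuous")
    ))
}
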