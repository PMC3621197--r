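#' Build the covariate design matrix
#'
#' Base model: intercept, centered age, age^2, male indicator, age x sex,
#' age^2 x sex, smoking (former, current vs never), education (>=12 years vs
#' <12), obesity (BMI >= 30 vs < 30), alcohol (former, current vs never),
#' region (OK, DK vs AZ), and log total arsenic (ug/g creatinine). Age is
#' centered at the sample mean before polynomials and interactions are formed,
#' to reduce collinearity. Sensitivity variants alter single terms:
#' \describe{
#'   \item{base}{the model above}
#'   \item{bmi_continuous}{BMI enters as one continuous column}
#'   \item{bmi_sex_interaction}{adds obesity x sex}
#'   \item{selenium_adjusted}{adds log urine selenium (ug/g)}
#'   \item{creatinine_covariate}{total arsenic in ug/L with log creatinine
#'     as an additional covariate (dilution modelled, not divided out)}
#'   \item{no_dilution}{total arsenic in ug/L, no dilution adjustment}
#' }
#'
#' @param cov data frame with columns `age` (years), `sex` ("M"/"F"),
#'   `education` ("lt12"/"ge12"), `bmi` (kg/m2), `smoking` and `alcohol`
#'   ("never"/"former"/"current"), `region` ("AZ"/"OK"/"DK"),
#'   `total_arsenic` (ug/g), `creatinine` (g/L), and for the relevant
#'   variants `selenium` (ug/g)
#' @param variant one of the model variants above
#' @return numeric design matrix with an intercept column and deterministic
#'   column names; indicator columns for factor levels absent from the
#'   sample are dropped so the matrix stays full rank
#' @export
build_design_matrix <- function(cov, variant = "base") {
  variant <- match.arg(variant, c("base", "bmi_continuous",
                                  "bmi_sex_interaction", "selenium_adjusted",
                                  "creatinine_covariate", "no_dilution"))
  chk_levels <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad) > 0)
      stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "))
    factor(as.character(x), levels = levels)
  }
  sex <- chk_levels(cov$sex, c("F", "M"), "sex")
  smoking <- chk_levels(cov$smoking, c("never", "former", "current"),
                        "smoking")
  alcohol <- chk_levels(cov$alcohol, c("never", "former", "current"),
                        "alcohol")
  education <- chk_levels(cov$education, c("lt12", "ge12"), "education")
  region <- chk_levels(cov$region, c("AZ", "OK", "DK"), "region")
  if (any(cov$age <= 0)) stop("age must be positive")

  age_c <- cov$age - mean(cov$age)
  male <- as.numeric(sex == "M")
  X <- cbind(
    "(Intercept)" = 1,
    age = age_c,
    age2 = age_c^2,
    sexM = male,
    "age:sexM" = age_c * male,
    "age2:sexM" = age_c^2 * male,
    smokingformer = as.numeric(smoking == "former"),
    smokingcurrent = as.numeric(smoking == "current"),
    educationge12 = as.numeric(education == "ge12"),
    alcoholformer = as.numeric(alcohol == "former"),
    alcoholcurrent = as.numeric(alcohol == "current"),
    regionOK = as.numeric(region == "OK"),
    regionDK = as.numeric(region == "DK"))

  X <- switch(variant,
    bmi_continuous = cbind(X, bmi = cov$bmi),
    cbind(X, bmi30 = as.numeric(cov$bmi >= 30)))
  if (variant == "bmi_sex_interaction")
    X <- cbind(X, "bmi30:sexM" = as.numeric(cov$bmi >= 30) * male)

  if (variant %in% c("creatinine_covariate", "no_dilution")) {
    tas_ugL <- cov$total_arsenic * cov$creatinine
    X <- cbind(X, log_total_as = log(tas_ugL))
    if (variant == "creatinine_covariate")
      X <- cbind(X, log_creatinine = log(cov$creatinine))
  } else {
    X <- cbind(X, log_total_as = log(cov$total_arsenic))
  }
  if (variant == "selenium_adjusted") {
    if (is.null(cov$selenium)) stop("selenium column required for variant")
    X <- cbind(X, log_selenium = log(cov$selenium))
  }
  # indicator columns for factor levels absent from the sample (possible in
  # small or stratified samples) are constant and would make the design
  # singular; drop them
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::var) > 0)
  X[, keep, drop = FALSE]
}

#' First-stage covariate adjustment under a polygenic model
#'
#' Estimates the fixed effects jointly with a polygenic variance component by
#' ML (GLS profiling of beta inside the variance-component likelihood), then
#' returns marginal residuals trait - X beta-hat and the fraction of trait
#' variance explained by the fitted covariates,
#' 1 - var(residuals) / var(trait).
#'
#' @param trait logit-scale trait vector
#' @param X full-rank design matrix from [build_design_matrix()]
#' @param phi kinship matrix for the same individuals
#' @return list with `residuals`, `beta`, `pct_variance_explained`, `fit`
#' @export
first_stage_adjust <- function(trait, X, phi) {
  model <- vc_model(trait, list(additive = 2 * phi), X = X)
  fit <- fit_ml(model, se = FALSE)
  pred <- drop(X %*% fit$beta)
  res <- trait - pred
  list(residuals = res,
       beta = stats::setNames(fit$beta, colnames(X)),
       pct_variance_explained = 1 - stats::var(res) / stats::var(trait),
       fit = fit)
}

#' Two-stage trait transformation
#'
#' The full pipeline applied to one species percentage: logit transform,
#' first-stage covariate adjustment under the polygenic model, then
#' rank-based inverse normal transformation of the residuals. The inverse
#' normal scores are rescaled to unit sample variance (a rank-preserving
#' affine step) so the final trait has mean 0 and variance 1 exactly; it
#' enters the second-stage variance-component model with an intercept only.
#'
#' @param pct species percentage vector in (0, 100)
#' @param cov covariate data frame (see [build_design_matrix()])
#' @param phi kinship matrix
#' @param variant covariate model variant
#' @return list with `final_trait`, `stage1_residuals`,
#'   `pct_variance_explained`, `kurtosis` (excess kurtosis of the final
#'   trait), and the stage-1 `beta`
#' @export
transform_trait <- function(pct, cov, phi, variant = "base") {
  lg <- logit_percent(pct)
  X <- build_design_matrix(cov, variant)
  s1 <- first_stage_adjust(lg, X, phi)
  z <- inverse_normal(s1$residuals)
  z <- (z - mean(z)) / stats::sd(z)
  list(final_trait = z,
       stage1_residuals = s1$residuals,
       pct_variance_explained = s1$pct_variance_explained,
       kurtosis = excess_kurtosis(z),
       beta = s1$beta)
}

#' Sample excess kurtosis
#' @param x numeric vector
#' @return m4/m2^2 - 3 using central moments
#' @export
excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  m4 / m2^2 - 3
}
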