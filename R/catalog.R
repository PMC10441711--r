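#' Canonical catalogue of the 19 chronic conditions
#'
#' Returns the fixed, ordered list of the 19 self-reported morbidities used
#' throughout the package. The order is part of the package contract: it
#' defines node indexing in every network, ground truth, and serialised
#' artifact.
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' disease_catalog()
disease_catalog <- function() {
  c("hypertension", "back_problems", "high_cholesterol", "cataract",
    "arthritis_rheumatism", "depression", "diabetes", "osteoporosis",
    "heart_problems", "glaucoma", "copd", "haemorrhagic_stroke", "cancer",
    "asthma", "renal_failure", "diabetic_retinopathy", "macular_degeneration",
    "parkinsons", "alzheimers")
}

#' Levels used for the stratification variables
#' @keywords internal
sex_levels <- function() c("female", "male")

#' @rdname sex_levels
#' @keywords internal
age_levels <- function() c("50-59", "60-74", "75+")

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Draw B sub-stream seeds (< 2^31) from a master seed, so that replicated
# procedures are reproducible replicate-by-replicate.
substream_seeds <- function(seed, B) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, B))
}

logit <- function(p) log(p / (1 - p))

expit <- function(x) stats::plogis(x)
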