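#' Reference statistics for vervet alarm and aggression calls
#'
#' Built-in reference tables from the quantitative study of free-ranging
#' vervet monkey calls that this package operationalises: per-context
#' descriptive statistics (mean and standard error of the mean over calls)
#' of the ten analysis variables, and the cross-validated discriminant
#' classification count tables. Female East African calls span five contexts
#' (between-group aggression, within-group aggression, aerial predator,
#' snake, terrestrial predator; 216/53/38/33/164 calls, 504 in total);
#' male East African alarm calls span the three predator contexts
#' (21/41/175 calls, 237 in total).
#'
#' These tables serve two purposes: they parameterise the synthetic-call
#' generator (SEMs are converted to per-call SDs via `sem * sqrt(n)`), and
#' the classification counts provide fixed arithmetic checks for
#' [confusion_report()].
#'
#' @param sex `"female"` (five contexts) or `"male"` (three predator
#'   contexts, East African males).
#' @return `vervet_descriptives()`: a data.frame with columns `variable`,
#'   `context`, `mean`, `sem`, `n`. `vervet_confusion()`: an integer matrix
#'   of cross-validated classification counts (rows = true context,
#'   columns = predicted). `vervet_context_n()`: named integer vector of
#'   per-context call counts.
#' @export
vervet_descriptives <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  v <- call_feature_vars()
  if (sex == "female") {
    contexts <- .female_contexts
    means <- c( # columns: agg_between, agg_within, aerial, snake, terrestrial
      4.3,    3.4,    2.7,    4.1,    1.4,
      38.9,   39.1,   43.9,   38.3,   107.7,
      0.68,   0.66,   0.53,   0.72,   0.62,
      1715,   1456,   986,    2840,   2374,
      1707,   1559,   990,    2634,   2224,
      3402,   2871,   1743,   3867,   2981,
      2106,   1617,   686,    1588,   1085,
      7048,   6126,   3793,   7162,   4092,
      1306,   1084,   933,    1640,   2207,
      509,    527,    659,    450,    1233)
    sems <- c(
      0.1,  0.2,  0.1,  0.3,  0.1,
      0.7,  1.0,  2.8,  1.3,  2.3,
      0.01, 0.01, 0.02, 0.01, 0.01,
      90,   140,  54,   115,  31,
      48,   77,   47,   71,   25,
      92,   124,  100,  103,  37,
      150,  174,  104,  215,  64,
      171,  268,  310,  198,  80,
      57,   101,  53,   157,  34,
      13,   26,   38,   29,   29)
  } else {
    contexts <- .male_contexts
    means <- c( # columns: aerial, snake, terrestrial
      4.2,   5.1,   3.1,
      76.5,  61.1,  112.0,
      0.37,  0.55,  0.60,
      1090,  1639,  1904,
      916,   1435,  1753,
      1311,  2282,  2393,
      543,   1503,  654,
      1832,  4069,  3794,
      1048,  1248,  1776,
      1278,  784,   819)
    sems <- c(
      0.4,  0.6,  0.2,
      4.6,  4.6,  2.0,
      0.02, 0.01, 0.01,
      88,   118,  22,
      60,   82,   18,
      54,   116,  24,
      94,   169,  35,
      99,   264,  47,
      98,   92,   27,
      55,   79,   14)
  }
  n <- vervet_context_n(sex)
  data.frame(variable = rep(v, each = length(contexts)),
             context = rep(contexts, times = length(v)),
             mean = means, sem = sems, n = unname(n[contexts]),
             stringsAsFactors = FALSE)
}

.female_contexts <- c("agg_between", "agg_within", "aerial", "snake",
                      "terrestrial")
.male_contexts <- c("aerial", "snake", "terrestrial")

#' @rdname vervet_descriptives
#' @export
vervet_context_n <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female")
    c(agg_between = 216L, agg_within = 53L, aerial = 38L, snake = 33L,
      terrestrial = 164L)
  else
    c(aerial = 21L, snake = 41L, terrestrial = 175L)
}

#' @rdname vervet_descriptives
#' @export
vervet_confusion <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female") {
    m <- matrix(c(119, 49, 37, 10, 1,
                  14,  25, 11, 3,  0,
                  1,   6,  31, 0,  0,
                  0,   3,  0,  30, 0,
                  0,   0,  1,  8,  155),
                nrow = 5, byrow = TRUE,
                dimnames = list(true = .female_contexts,
                                predicted = .female_contexts))
  } else {
    m <- matrix(c(18, 3,  0,
                  7,  31, 3,
                  0,  3,  172),
                nrow = 3, byrow = TRUE,
                dimnames = list(true = .male_contexts,
                                predicted = .male_contexts))
  }
  storage.mode(m) <- "integer"
  m
}
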