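# Shared fixtures, built in code.

# 12-row boundary table: every quoted classification threshold is hit exactly
# on at least one row, together with the hand-derived expected flags.
boundary_fixture <- function() {
  records <- tibble::tribble(
    ~id, ~sex,     ~waist, ~tg,   ~hdl,  ~sbp,  ~dbp,  ~bp_treatment, ~glucose, ~bmi,  ~hba1c, ~glucose_med, ~t1dm_diag, ~t2dm_diag, ~agatston,
    1L,  "male",    102,    1.0,   1.5,   120,    70,    0,             5.0,      25,    5.0,    0,            0,          0,          0,
    2L,  "female",   88,    1.7,   1.3,   129.9,  84.9,  0,             5.59,     29.99, 6.49,   0,            0,          0,          0,
    3L,  "male",    101.9,  1.71,  1.0,   130,    84.9,  0,             5.6,      30,    6.5,    0,            0,          0,          1,
    4L,  "female",   87.9,  2.0,   1.29,  129,    85,    0,             7.0,      31,    5.0,    0,            0,          0,          5,
    5L,  "male",     90,    1.69,  0.99,  129,    84,    1,             6.9,      28,    6.4,    0,            0,          0,          0,
    6L,  "female",   70,    1.0,   1.31,  NA,     NA,    1,             4.0,      20,    5.0,    0,            0,          0,          0,
    7L,  "male",     80,    1.2,   1.01,  NA,     NA,    0,             4.5,      22,    5.2,    0,            0,          0,          0,
    8L,  "female",   60,    0.8,   1.4,   110,    60,    0,             5.0,      21,    5.1,    1,            0,          0,          0,
    9L,  "male",     85,    1.3,   1.2,   112,    64,    0,             5.2,      24,    5.3,    1,            1,          0,          0,
    10L, "female",   75,    1.1,   1.35,  108,    62,    0,             4.8,      23,    5.0,    0,            0,          1,          0,
    11L, "male",     95,    1.5,   1.1,   128,    84,    0,             5.59,     29,    6.49,   0,            0,          0,          0,
    12L, "female",  100,    5.0,   0.5,   160,   100,    1,            11.0,      40,    9.0,    1,            0,          1,          400
  )
  expected <- tibble::tribble(
    ~id, ~abdominal_obesity, ~hypertriglyceridemia, ~low_hdl, ~high_bp, ~hyperglycaemia, ~obesity, ~t2dm, ~cac_present,
    1L,  1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
    2L,  1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
    3L,  0L, 1L, 0L, 1L, 1L, 1L, 1L, 1L,
    4L,  0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
    5L,  0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L,
    6L,  0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L,
    7L,  0L, 0L, 0L, NA_integer_, 0L, 0L, 0L, 0L,
    8L,  0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L,
    9L,  0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
    10L, 0L, 0L, 0L, 0L, 1L, 0L, 1L, 0L,
    11L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
    12L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L
  )
  list(records = records, expected = expected)
}

# Tiny harmonization fixtures.
exposure_3snp <- function() {
  tibble::tibble(
    rsid = c("rs1153858", "rs1047891", "rs37369"),
    effect_allele = c("A", "A", "T"), other_allele = c("G", "C", "C"),
    beta = c(0.25, 0.17, 0.155), se = c(0.014, 0.014, 0.014),
    pvalue = 1e-10, n = 5143L, eaf = 0.3
  )
}

# A standardized matrix made of `blocks` mutually independent blocks of
# `copies` duplicated columns each. The base columns are taken as principal
# component scores of a random matrix so they are exactly uncorrelated and
# the sample correlation matrix has the ideal block structure.
duplicated_block_matrix <- function(blocks, copies, n = 200, seed = 42) {
  set.seed(seed)
  base <- stats::prcomp(matrix(rnorm(n * (blocks + 2)), n, blocks + 2))$x[, seq_len(blocks)]
  base <- scale(base)
  out <- base[, rep(seq_len(blocks), each = copies), drop = FALSE]
  colnames(out) <- paste0("met_", seq_len(ncol(out)))
  out
}

# At-risk table with a binary exposure for the 2x2 logistic identity:
# exposed 20 events / 80 non-events, unexposed 10 / 90.
binary_exposure_fixture <- function() {
  tibble::tibble(
    sex = "male",
    exposed = rep(c(1, 0), each = 100),
    event = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  )
}

# Exhaustive add/drop neighbour oracle: AIC of every model one move away.
neighbour_aics <- function(data, response, candidates, selected) {
  fit_aic <- function(terms) {
    fml <- if (length(terms)) {
      as.formula(paste(response, "~", paste(terms, collapse = " + ")))
    } else {
      as.formula(paste(response, "~ 1"))
    }
    AIC(lm(fml, data = data))
  }
  adds <- setdiff(candidates, selected)
  drops <- selected
  c(
    vapply(adds, function(t) fit_aic(c(selected, t)), numeric(1)),
    vapply(drops, function(t) fit_aic(setdiff(selected, t)), numeric(1))
  )
}

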