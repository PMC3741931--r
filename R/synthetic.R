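# Synthetic cohort generator.
#
# The default configuration emulates a 493-patient operation-centric OSCC
# registry: per-attribute category counts are specified separately for the
# >36-month stratum (n = 271) and the <=36-month stratum (n = 222), and
# attributes are sampled independently within each stratum (exact-count
# permutation). Attributes whose per-stratum counts fall short of the
# stratum size have the remainder assigned an explicit missing value, as
# in real registries. An optional planted itemset installs a joint
# association among chosen attributes of the >36 stratum whose expected
# joint frequency is the independence product times `planted_boost`.

# per-stratum category counts: list(attr = matrix(categories x c(gt36, le36)))
.table1_counts <- function() {
  mk <- function(cats, gt36, le36) {
    matrix(c(gt36, le36), ncol = 2, dimnames = list(cats, c("gt36", "le36")))
  }
  list(
    age_group = mk(c("<30", "30~50", "50~70", ">70"),
      c(3, 125, 129, 14), c(4, 103, 107, 8)),
    primary_site = mk(
      c("lip", "cheek mucosa", "gum", "tongue", "mouth floor",
        "palate", "retromolar", "vestibule", "nonspecific"),
      c(24, 103, 25, 88, 11, 3, 15, 1, 1),
      c(12, 81, 17, 87, 8, 2, 12, 1, 2)),
    laterality = mk(c("00", "01", "02", "03", "04"),
      c(22, 123, 123, 3, 0), c(15, 107, 100, 0, 0)),
    grade = mk(c("01", "02", "03", "04", "09"),
      c(156, 60, 5, 1, 49), c(131, 63, 2, 0, 26)),
    nodes_group = mk(c("<5", "5~10", ">10"),
      c(160, 45, 65), c(125, 28, 69)),
    clinical_stage = mk(paste("Stage", 0:4),
      c(0, 79, 47, 69, 50), c(4, 62, 26, 62, 32)),
    pathologic_stage = mk(paste("Stage", 0:4),
      c(2, 112, 52, 15, 24), c(0, 103, 40, 16, 34)),
    clinical_size_group = mk(c("<2 cm", "2~4 cm", ">4 cm"),
      c(100, 134, 19), c(62, 110, 14)),
    pathology_size_group = mk(c("<2 cm", "2~4 cm", ">4 cm"),
      c(114, 94, 14), c(83, 89, 11)),
    op_group = mk(c("01", "02", "03"),
      c(238, 14, 19), c(147, 13, 62))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The default (no arguments) emulates the 493-patient registry the
#' analysis layer expects: 271 patients surviving beyond 36 months, 222
#' not, with the per-stratum category counts of the default marginal
#' table. For other cohort sizes the default counts are rescaled to
#' probabilities and sampled.
#'
#' @param n total number of patients.
#' @param n_gt36 number of patients in the >36-month stratum; default
#'   scales 271/493.
#' @param marginals list of per-attribute count matrices (categories x
#'   `c("gt36", "le36")`); default is the registry table.
#' @param planted_itemset named character vector of
#'   `attribute = value` pairs to associate within the >36 stratum, e.g.
#'   `c(grade = "02", primary_site = "tongue")`; `NULL` for none.
#' @param planted_boost multiplicative joint-frequency factor (>= 1): the
#'   planted pattern's expected joint frequency in the >36 stratum equals
#'   the product of its marginal frequencies times this factor.
#' @return object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config()
#' cfg$n
#' @export
synthetic_config <- function(n = 493L, n_gt36 = NULL, marginals = NULL,
                             planted_itemset = NULL, planted_boost = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (is.null(n_gt36)) n_gt36 <- as.integer(round(n * 271 / 493))
  n_gt36 <- as.integer(n_gt36)
  stopifnot(n_gt36 >= 0, n_gt36 <= n)
  if (is.null(marginals)) marginals <- .table1_counts()
  exact <- n == sum(marginals[[1]][, "gt36"]) + sum(marginals[[1]][, "le36"]) &&
    n_gt36 == sum(marginals[[1]][, "gt36"])
  if (planted_boost < 1) stop("planted_boost must be >= 1")
  if (!is.null(planted_itemset)) {
    bad <- setdiff(names(planted_itemset), names(marginals))
    if (length(bad) > 0) stop("planted attribute(s) not in marginals: ",
      paste(bad, collapse = ", "))
    for (a in names(planted_itemset)) {
      if (!planted_itemset[[a]] %in% rownames(marginals[[a]])) {
        stop("planted value '", planted_itemset[[a]], "' not a category of ", a)
      }
    }
  }
  structure(
    list(n = n, n_gt36 = n_gt36, marginals = marginals, exact = exact,
      planted_itemset = planted_itemset, planted_boost = planted_boost),
    class = "synthetic_config"
  )
}

# mixture weight z such that the planted pattern's expected joint
# frequency equals q = boost * prod(p): with probability z a record takes
# the full pattern; otherwise its planted attributes are drawn
# independently from the adjusted marginals (p_a - z) / (1 - z).
.planted_weight <- function(p, boost) {
  q <- boost * prod(p)
  if (q > min(p) + 1e-12) {
    stop(sprintf(
      "infeasible planted_boost: joint frequency %.4f exceeds marginal %.4f",
      q, min(p)))
  }
  if (boost <= 1) return(0)
  f <- function(z) z + prod(p - z) / (1 - z)^(length(p) - 1) - q
  stats::uniroot(f, lower = 0, upper = min(p) - 1e-12, tol = 1e-12)$root
}

# exact-count label permutation for one attribute in one stratum
.labels_exact <- function(cats, counts, n_s) {
  v <- c(rep(cats, counts), rep(NA_character_, n_s - sum(counts)))
  sample(v)
}

.labels_prob <- function(cats, counts, n_s, n_source) {
  p <- counts / n_source
  miss <- max(0, 1 - sum(p))
  sample(c(cats, NA_character_), n_s, replace = TRUE, prob = c(p, miss))
}

# generate discretized-label columns for one stratum
.stratum_labels <- function(config, stratum, n_s) {
  marg <- config$marginals
  planted <- config$planted_itemset
  labels <- list()
  plant_here <- stratum == "gt36" && !is.null(planted) && config$planted_boost > 1
  pattern_rows <- integer(0)
  if (plant_here && n_s > 0) {
    p <- vapply(names(planted),
      function(a) marg[[a]][planted[[a]], "gt36"] / sum(marg[[a]][, "gt36"]),
      numeric(1))
    z <- .planted_weight(p, config$planted_boost)
    J <- round(z * n_s)
    pattern_rows <- sample.int(n_s, J)
  }
  for (a in names(marg)) {
    cnts <- marg[[a]][, stratum]
    cats <- rownames(marg[[a]])
    n_source <- sum(marg[[a]][, stratum])
    col <- rep(NA_character_, n_s)
    if (plant_here && a %in% names(planted)) {
      col[pattern_rows] <- planted[[a]]
      rest <- setdiff(seq_len(n_s), pattern_rows)
      cnts2 <- cnts
      if (config$exact) {
        cnts2[planted[[a]]] <- cnts2[planted[[a]]] - length(pattern_rows)
        if (cnts2[planted[[a]]] < 0) stop("planted count exceeds marginal count")
        col[rest] <- .labels_exact(cats, cnts2, length(rest))
      } else {
        # adjusted marginals keep the attribute's overall frequencies
        p_all <- cnts / n_source
        z_eff <- length(pattern_rows) / n_s
        p_adj <- p_all / (1 - z_eff)
        p_adj[planted[[a]]] <- (p_all[planted[[a]]] - z_eff) / (1 - z_eff)
        p_adj <- pmax(p_adj, 0)
        col[rest] <- sample(c(cats, NA_character_), length(rest),
          replace = TRUE, prob = c(p_adj, max(0, 1 - sum(p_adj))))
      }
    } else {
      col <- if (config$exact) {
        .labels_exact(cats, cnts, n_s)
      } else {
        .labels_prob(cats, cnts, n_s, n_source)
      }
    }
    labels[[a]] <- col
  }
  labels
}

# map category labels back to raw record values
.raw_from_labels <- function(lab, stratum, n_s, id_offset) {
  draw_age <- function(g) switch(g,
    "<30" = sample(18:29, 1), "30~50" = sample(30:50, 1),
    "50~70" = sample(51:70, 1), ">70" = sample(71:90, 1), NA_integer_)
  draw_nodes <- function(g) switch(g,
    "<5" = sample(0:4, 1), "5~10" = sample(5:10, 1),
    ">10" = sample(11:40, 1), NA_integer_)
  draw_size <- function(g) switch(g,
    "<2 cm" = round(stats::runif(1, 0.4, 1.9), 1),
    "2~4 cm" = round(stats::runif(1, 2.0, 4.0), 1),
    ">4 cm" = round(stats::runif(1, 4.1, 8.0), 1), NA_real_)
  draw_treatment <- function(g) switch(g,
    "01" = "OP", "02" = "OP->IA",
    "03" = sample(.op03_sequences, 1), "OP")
  stage_int <- function(s) {
    ifelse(is.na(s), NA_integer_, as.integer(sub("Stage ", "", s)))
  }
  months <- if (stratum == "gt36") {
    round(stats::runif(n_s, 37, 120), 1)
  } else {
    round(stats::runif(n_s, 1, 36), 1)
  }
  chr1 <- function(f, x) vapply(x, function(v) {
    if (is.na(v)) NA_character_ else as.character(f(v))
  }, character(1))
  num1 <- function(f, x) vapply(x, function(v) {
    if (is.na(v)) NA_real_ else as.numeric(f(v))
  }, numeric(1))
  data.frame(
    patient_id = sprintf("P%04d", id_offset + seq_len(n_s)),
    age = num1(draw_age, lab$age_group),
    primary_site = lab$primary_site,
    laterality = num1(as.integer, lab$laterality),
    grade = num1(as.integer, lab$grade),
    nodes_examined = num1(draw_nodes, lab$nodes_group),
    clinical_stage = stage_int(lab$clinical_stage),
    pathologic_stage = stage_int(lab$pathologic_stage),
    clinical_tumor_size = num1(draw_size, lab$clinical_size_group),
    pathology_tumor_size = num1(draw_size, lab$pathology_size_group),
    treatment_sequence = chr1(draw_treatment, lab$op_group),
    survival_months = months,
    vital_status = ifelse(months >= 60, "alive", "dead"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws raw patient records whose discretized labels reproduce the
#' configured per-stratum category counts (exactly, when the configuration
#' is in exact-count mode; within sampling error otherwise), with survival
#' months consistent with each record's stratum. When a planted itemset is
#' configured, its joint frequency among >36-month survivors equals the
#' independence product times `planted_boost` in expectation while each
#' attribute's marginal counts are preserved.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return data frame of raw patient records ([discretize()]-ready).
#' @examples
#' rec <- generate_cohort(synthetic_config(), seed = 7)
#' nrow(rec)
#' @export
generate_cohort <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  parts <- list()
  offs <- 0L
  for (stratum in c("gt36", "le36")) {
    n_s <- if (stratum == "gt36") config$n_gt36 else config$n - config$n_gt36
    if (n_s == 0) next
    lab <- .stratum_labels(config, stratum, n_s)
    parts[[stratum]] <- .raw_from_labels(lab, stratum, n_s, offs)
    offs <- offs + n_s
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- .raw_from_labels(list(), "gt36", 0L, 0L)
  }
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
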