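#' @name discretization
#' @title Discretization scheme for clinical attributes
#'
#' @description
#' Raw patient records carry continuous or coded attributes (age in years,
#' tumour sizes in cm, lymph-node counts, AJCC stage 0--4, treatment
#' sequences). Analysis runs on categorical labels. The scheme implemented
#' here is:
#'
#' * `age_group`: `<30`, `30~50` (30--50 inclusive), `50~70` (over 50 up to
#'   70), `>70`;
#' * `nodes_group`: `<5`, `5~10` (5--10 inclusive), `>10` regional lymph
#'   nodes examined;
#' * tumour-size groups (clinical and pathology): `<2 cm`, `2~4 cm`
#'   (2--4 cm inclusive), `>4 cm`;
#' * `clinical_stage_group` / `pathologic_stage_group`: stages 0--3 are
#'   `early`, stage 4 is `late` (see [stage_group()]);
#' * `laterality`: zero-padded code `00`--`04`;
#' * `grade`: zero-padded differentiation code `01`, `02`, `03`, `04`, `09`;
#' * `op_group`: `01` = operation only, `02` = operation then intra-arterial
#'   chemotherapy, `03` = operation followed by any other listed adjuvant
#'   sequence (chemo- and/or radiotherapy);
#' * `group`: constant `OP` for operation-initial records;
#' * `survived_gt36`: `TRUE` iff `survival_months > 36`;
#' * `five_year_survivor`: `TRUE` iff `survival_months >= 60`, `FALSE` for
#'   patients who died earlier, `NA` for patients alive but censored before
#'   60 months.
#'
#' Interior bins are closed on both ends (a 2.0 cm tumour is `2~4 cm`, a
#' 50-year-old is `30~50`); this boundary convention is deterministic and
#' documented here once.
#'
#' Missing raw values yield `NA` labels, never empty strings.
NULL

# treatment sequences assigned to op_group "03" (canonical "->" / "+" form)
.op03_sequences <- c(
  "OP->CT", "OP->CT+IV", "OP->CT->RT", "OP->IA->RT", "OP->IV",
  "OP->IV->RT", "OP->RT", "OP->RT+CT", "OP->RT+IV", "OP->RT->CT",
  "OP->RT->IA", "OP->RT->IV"
)

.treatment_tokens <- c("OP", "IA", "CT", "IV", "RT")

# normalize a treatment-sequence string: unicode arrows, spacing, case
.normalize_treatment <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  gsub("→", "->", x)
}

# split into modality steps; combination steps keep "+"
.treatment_steps <- function(x) strsplit(.normalize_treatment(x), "->", fixed = TRUE)

#' Map a clinical or pathologic stage code to early/late
#'
#' Stages 0 through 3 are grouped as `early`; stage 4 is `late`.
#'
#' @param stage integer vector of stage codes in 0--4 (NA allowed).
#' @return character vector of `"early"` / `"late"` labels.
#' @examples
#' stage_group(c(0, 3, 4))
#' @export
stage_group <- function(stage) {
  ok <- is.na(stage) | (stage %in% 0:4)
  if (!all(ok)) {
    stop("stage codes out of range 0-4: ", paste(unique(stage[!ok]), collapse = ", "))
  }
  ifelse(is.na(stage), NA_character_, ifelse(stage == 4, "late", "early"))
}

.bin_age <- function(age) {
  ifelse(is.na(age), NA_character_,
    ifelse(age < 30, "<30",
      ifelse(age <= 50, "30~50",
        ifelse(age <= 70, "50~70", ">70"))))
}

.bin_nodes <- function(n) {
  ifelse(is.na(n), NA_character_,
    ifelse(n < 5, "<5", ifelse(n <= 10, "5~10", ">10")))
}

.bin_size <- function(cm) {
  ifelse(is.na(cm), NA_character_,
    ifelse(cm < 2, "<2 cm", ifelse(cm <= 4, "2~4 cm", ">4 cm")))
}

.code2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%02d", as.integer(x)))

.op_group_of <- function(seq_str) {
  s <- .normalize_treatment(seq_str)
  ifelse(is.na(s) | s == "", NA_character_,
    ifelse(s == "OP", "01",
      ifelse(s == "OP->IA", "02",
        ifelse(s %in% .op03_sequences, "03", NA_character_))))
}

#' Discretize raw patient records into a categorical cohort table
#'
#' Applies the package's discretization scheme (see [discretization]) to a
#' data frame of raw patient records as returned by [read_cohort()] or
#' [generate_cohort()]. Treatment sequences outside the enumerated
#' operation-initial set yield `op_group = NA`; such records are flagged
#' (and counted in a message) but retained for analyses that do not use
#' `op_group`.
#'
#' @param records data frame of raw patient records with columns
#'   `patient_id`, `age`, `primary_site`, `laterality`, `grade`,
#'   `nodes_examined`, `clinical_stage`, `pathologic_stage`,
#'   `clinical_tumor_size`, `pathology_tumor_size`, `treatment_sequence`,
#'   `survival_months`, `vital_status`.
#' @return a data frame of class `cohort_table`, one row per input record,
#'   with categorical columns `age_group`, `primary_site`, `laterality`,
#'   `grade`, `nodes_group`, `clinical_stage_group`,
#'   `pathologic_stage_group`, `clinical_size_group`,
#'   `pathology_size_group`, `op_group`, `group`, and logical columns
#'   `survived_gt36`, `five_year_survivor`.
#' @seealso [stage_group()], [encode_transactions()], [filter_population()]
#' @examples
#' rec <- generate_cohort(synthetic_config(n = 40), seed = 1)
#' head(discretize(rec))
#' @export
discretize <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c(
    "patient_id", "age", "primary_site", "laterality", "grade",
    "nodes_examined", "clinical_stage", "pathologic_stage",
    "clinical_tumor_size", "pathology_tumor_size", "treatment_sequence",
    "survival_months", "vital_status"
  )
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) stop("records lack columns: ", paste(miss, collapse = ", "))

  op_grp <- .op_group_of(records$treatment_sequence)
  n_unmapped <- sum(is.na(op_grp) & !is.na(records$treatment_sequence) &
    records$treatment_sequence != "")
  if (n_unmapped > 0) {
    .msg(n_unmapped, " record(s) with unmapped treatment sequence; op_group set to NA")
  }
  starts_op <- vapply(
    .treatment_steps(records$treatment_sequence),
    function(s) length(s) > 0 && !is.na(s[1]) && s[1] == "OP", logical(1)
  )

  site <- ifelse(is.na(records$primary_site) | records$primary_site == "",
    NA_character_, tolower(trimws(records$primary_site)))

  out <- data.frame(
    patient_id = as.character(records$patient_id),
    age_group = .bin_age(records$age),
    primary_site = site,
    laterality = .code2(records$laterality),
    grade = .code2(records$grade),
    nodes_group = .bin_nodes(records$nodes_examined),
    clinical_stage_group = stage_group(records$clinical_stage),
    pathologic_stage_group = stage_group(records$pathologic_stage),
    clinical_size_group = .bin_size(records$clinical_tumor_size),
    pathology_size_group = .bin_size(records$pathology_tumor_size),
    op_group = op_grp,
    group = ifelse(starts_op, "OP", NA_character_),
    survived_gt36 = records$survival_months > 36,
    five_year_survivor = ifelse(records$survival_months >= 60, TRUE,
      ifelse(records$vital_status == "dead", FALSE, NA)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Subset a cohort table by survival stratum
#'
#' @param cohort a `cohort_table` from [discretize()].
#' @param predicate one of `"survived_gt36"`, `"not_survived_gt36"`,
#'   `"all"`.
#' @return the filtered cohort (record order preserved); the resulting size
#'   is reported in a message.
#' @examples
#' coh <- discretize(generate_cohort(synthetic_config(n = 40), seed = 1))
#' nrow(filter_population(coh, "survived_gt36"))
#' @export
filter_population <- function(cohort,
                              predicate = c("survived_gt36", "not_survived_gt36", "all")) {
  predicate <- match.arg(predicate)
  keep <- switch(predicate,
    survived_gt36 = cohort$survived_gt36 %in% TRUE,
    not_survived_gt36 = cohort$survived_gt36 %in% FALSE,
    all = rep(TRUE, nrow(cohort))
  )
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  .msg("population '", predicate, "': ", nrow(out), " of ", nrow(cohort), " records")
  out
}
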