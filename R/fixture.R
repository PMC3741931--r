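# Deterministic 271-transaction benchmark fixture.
#
# Eleven joint counts over the four analysis attributes (grade = 02,
# primary_site = tongue, clinical_stage_group = early, group = OP) are
# fixed; the remaining cells of the 16-cell joint table are free. The
# free cells are resolved by exhaustive search for the lexicographically
# smallest non-negative integer solution (cells ordered by their
# (grade, tongue, early, OP) binary index), making the fixture fully
# deterministic. Note the constraints force 15 transactions without
# group = OP (e.g. 88 tongue but only 78 tongue-and-OP): the complement
# carries the synthetic label "other".

# the 11 fixed counts
.fixture_constraints <- function() {
  list(
    N = 271L,
    grade02 = 60L, tongue = 88L,
    grade02_early = 49L, grade02_op = 55L,
    tongue_early = 70L, tongue_op = 78L,
    tongue_early_op = 65L, grade02_early_op = 46L,
    grade02_tongue_early = 27L, grade02_tongue_early_op = 27L
  )
}

# counts for one candidate cell vector, indexed by 16 (g, t, e, o) patterns
.fixture_margins <- function(cells, g, t, e, o) {
  list(
    N = sum(cells),
    grade02 = sum(cells[g == 1]), tongue = sum(cells[t == 1]),
    grade02_early = sum(cells[g == 1 & e == 1]),
    grade02_op = sum(cells[g == 1 & o == 1]),
    tongue_early = sum(cells[t == 1 & e == 1]),
    tongue_op = sum(cells[t == 1 & o == 1]),
    tongue_early_op = sum(cells[t == 1 & e == 1 & o == 1]),
    grade02_early_op = sum(cells[g == 1 & e == 1 & o == 1]),
    grade02_tongue_early = sum(cells[g == 1 & t == 1 & e == 1]),
    grade02_tongue_early_op = sum(cells[g == 1 & t == 1 & e == 1 & o == 1])
  )
}

# Solve the joint table. Constraint propagation pins down every cell given
# two free integers (how the grade02/late/OP mass and the grade02/late
# mass split over the tongue axis); the four cells of the unconstrained
# (non-grade02, non-tongue) block only have their total fixed, and the
# lexicographically smallest split puts the whole total in the block's
# last cell. Both free integers are enumerated exhaustively over their
# bounds and every candidate is checked against all eleven constraints;
# the lexicographically smallest feasible cell vector (cells ordered by
# their (g, t, e, o) binary index) is returned.
.fixture_cells <- function() {
  con <- .fixture_constraints()
  g <- rep(0:1, each = 8)
  t <- rep(rep(0:1, each = 4), 2)
  e <- rep(rep(0:1, each = 2), 4)
  o <- rep(0:1, 8)
  cell_id <- function(gi, ti, ei, oi) which(g == gi & t == ti & e == ei & o == oi)

  go_late <- con$grade02_op - con$grade02_early_op    # grade02, late, OP mass
  g_late <- con$grade02 - con$grade02_early           # grade02, late mass
  t_late <- con$tongue - con$tongue_early             # tongue, late mass
  to_late <- con$tongue_op - con$tongue_early_op      # tongue, late, OP mass

  best <- NULL
  for (b in 0:go_late) {        # b = n(grade02, tongue, late, OP)
    for (cc in 0:g_late) {      # cc = n(grade02, tongue, late, no OP)
      cells <- integer(16)
      cells[cell_id(1, 1, 1, 1)] <- con$grade02_tongue_early_op
      cells[cell_id(1, 1, 1, 0)] <-
        con$grade02_tongue_early - con$grade02_tongue_early_op
      cells[cell_id(1, 0, 1, 1)] <- con$grade02_early_op - con$grade02_tongue_early_op
      cells[cell_id(1, 0, 1, 0)] <- con$grade02_early - con$grade02_tongue_early -
        cells[cell_id(1, 0, 1, 1)]
      cells[cell_id(0, 1, 1, 1)] <- con$tongue_early_op - con$grade02_tongue_early_op
      cells[cell_id(0, 1, 1, 0)] <- con$tongue_early - con$grade02_tongue_early -
        cells[cell_id(0, 1, 1, 1)]
      cells[cell_id(1, 1, 0, 1)] <- b
      cells[cell_id(1, 1, 0, 0)] <- cc
      cells[cell_id(1, 0, 0, 1)] <- go_late - b
      cells[cell_id(1, 0, 0, 0)] <- g_late - go_late - cc
      cells[cell_id(0, 1, 0, 1)] <- to_late - b
      cells[cell_id(0, 1, 0, 0)] <- t_late - to_late - cc
      # unconstrained block: lexicographically minimal split
      rest <- con$N - sum(cells)
      cells[cell_id(0, 0, 1, 1)] <- rest
      if (any(cells < 0)) next
      got <- .fixture_margins(cells, g, t, e, o)
      if (!identical(lapply(got, as.integer), lapply(con, as.integer))) next
      key <- cells[order(g * 8 + t * 4 + e * 2 + o)]
      if (is.null(best) || .lex_less(key, best$key)) {
        best <- list(cells = cells, key = key)
      }
    }
  }
  if (is.null(best)) stop("fixture constraints are infeasible")
  list(cells = best$cells, g = g, t = t, e = e, o = o)
}

.lex_less <- function(x, y) {
  d <- x - y
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' Deterministic transaction fixture with the benchmark joint counts
#'
#' Builds a 271-transaction database over the four analysis attributes
#' (`grade`, `clinical_stage_group`, `primary_site`, `group`) whose item
#' and joint itemset counts equal the eleven benchmark values: N = 271,
#' count(grade=02) = 60, count(primary_site=tongue) = 88,
#' count(grade=02, early) = 49, count(grade=02, OP) = 55,
#' count(tongue, early) = 70, count(tongue, OP) = 78,
#' count(tongue, early, OP) = 65, count(grade=02, early, OP) = 46,
#' count(grade=02, tongue, early) = 27 and
#' count(grade=02, tongue, early, OP) = 27. All eleven are re-verified by
#' an internal assertion at build time. Complement categories carry the
#' synthetic labels `grade=01`, `primary_site=other`,
#' `clinical_stage_group=late`, `group=other`.
#'
#' @return a [transaction_db()] with `N = 271`.
#' @examples
#' db <- build_table2_fixture()
#' db$N
#' @export
build_table2_fixture <- function() {
  sol <- .fixture_cells()
  cells <- sol$cells
  tx <- list()
  for (i in seq_along(cells)) {
    if (cells[i] == 0) next
    items <- c(
      paste0("grade=", if (sol$g[i] == 1) "02" else "01"),
      paste0("clinical_stage_group=", if (sol$e[i] == 1) "early" else "late"),
      paste0("primary_site=", if (sol$t[i] == 1) "tongue" else "other"),
      paste0("group=", if (sol$o[i] == 1) "OP" else "other")
    )
    tx <- c(tx, rep(list(items), cells[i]))
  }
  db <- transaction_db(tx)
  # assertion: recount the 11 constraints from the built transactions
  con <- .fixture_constraints()
  has <- function(...) {
    pat <- c(...)
    sum(vapply(db$transactions, function(t) all(match(pat, db$items) %in% t),
      logical(1)))
  }
  stopifnot(
    db$N == con$N,
    has("grade=02") == con$grade02,
    has("primary_site=tongue") == con$tongue,
    has("grade=02", "clinical_stage_group=early") == con$grade02_early,
    has("grade=02", "group=OP") == con$grade02_op,
    has("primary_site=tongue", "clinical_stage_group=early") == con$tongue_early,
    has("primary_site=tongue", "group=OP") == con$tongue_op,
    has("primary_site=tongue", "clinical_stage_group=early", "group=OP") ==
      con$tongue_early_op,
    has("grade=02", "clinical_stage_group=early", "group=OP") ==
      con$grade02_early_op,
    has("grade=02", "primary_site=tongue", "clinical_stage_group=early") ==
      con$grade02_tongue_early,
    has("grade=02", "primary_site=tongue", "clinical_stage_group=early",
      "group=OP") == con$grade02_tongue_early_op
  )
  db
}
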