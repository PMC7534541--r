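#' Space-group symmetry rules
#'
#' Provides the symmetry machinery needed to predict powder-pattern peak
#' positions: symmetry operators, systematic-absence (reflection-condition)
#' predicates and reflection multiplicities. Exactly the four space groups
#' observed for the screened in cellulo crystal phases are supported —
#' P41212 (No. 92), P4212 (No. 90), P42212 (No. 94) and P6522 (No. 179) —
#' plus generic primitive lattices with no reflection conditions
#' ("P-tetragonal", "P-hexagonal", "P-orthorhombic", "P-cubic"), whose
#' operators are the rotational holohedry so that multiplicities of general
#' lattice-plane families come out right.
#'
#' @param symbol Hermann–Mauguin symbol, one of `"P41212"`, `"P4212"`,
#'   `"P42212"`, `"P6522"` (screw-axis digits run together, e.g. "P41212" is
#'   P4_1 2_1 2), or a generic `"P-<system>"` symbol.
#' @return An object of class `space_group` with fields `symbol`, `system`,
#'   `operators` (list of `list(R = 3x3 integer matrix, t = translation)`) and
#'   `conditions` (a predicate data structure used by
#'   [is_systematically_absent()]).
#' @examples
#' sg <- space_group("P6522")
#' is_systematically_absent(sg, c(0, 0, 3))  # TRUE: 00l requires l = 6n
#' @export
space_group <- function(symbol) {
  key <- gsub("[ _]", "", tolower(symbol))
  spec <- .sg_table[[key]]
  if (is.null(spec)) {
    stop("unsupported space group '", symbol, "'; supported: ",
         paste(names(.sg_table), collapse = ", "), call. = FALSE)
  }
  structure(
    list(symbol = spec$symbol, system = spec$system,
         operators = spec$operators, conditions = spec$conditions),
    class = "space_group"
  )
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("<space_group> %s (%s), %d operators\n",
              x$symbol, x$system, length(x$operators)))
  invisible(x)
}

# ---- operator construction ------------------------------------------------

.op <- function(R, t = c(0, 0, 0)) list(R = matrix(as.numeric(R), 3, 3, byrow = TRUE), t = t)

# Rotation parts of the tetragonal 422 point group (IT standard setting).
.rot_422 <- list(
  c(1,0,0, 0,1,0, 0,0,1),    # 1
  c(-1,0,0, 0,-1,0, 0,0,1),  # 2 [001]
  c(0,-1,0, 1,0,0, 0,0,1),   # 4+ [001]
  c(0,1,0, -1,0,0, 0,0,1),   # 4- [001]
  c(-1,0,0, 0,1,0, 0,0,-1),  # 2 [010]
  c(1,0,0, 0,-1,0, 0,0,-1),  # 2 [100]
  c(0,1,0, 1,0,0, 0,0,-1),   # 2 [110]
  c(0,-1,0, -1,0,0, 0,0,-1)  # 2 [1-10]
)

# Rotation parts of the hexagonal 622 point group (hexagonal axes).
.rot_622 <- list(
  c(1,0,0, 0,1,0, 0,0,1),
  c(0,-1,0, 1,-1,0, 0,0,1),   # 3+
  c(-1,1,0, -1,0,0, 0,0,1),   # 3-
  c(-1,0,0, 0,-1,0, 0,0,1),   # 2 [001]
  c(0,1,0, -1,1,0, 0,0,1),    # 6-
  c(1,-1,0, 1,0,0, 0,0,1),    # 6+
  c(0,1,0, 1,0,0, 0,0,-1),    # 2 [110]
  c(1,-1,0, 0,-1,0, 0,0,-1),  # 2 [100]
  c(-1,0,0, -1,1,0, 0,0,-1),  # 2 [010]
  c(0,-1,0, -1,0,0, 0,0,-1),  # 2 [1-10]
  c(-1,1,0, 0,1,0, 0,0,-1),   # 2 [120]
  c(1,0,0, 1,-1,0, 0,0,-1)    # 2 [210]
)

.rot_222 <- list(
  c(1,0,0, 0,1,0, 0,0,1),
  c(-1,0,0, 0,-1,0, 0,0,1),
  c(1,0,0, 0,-1,0, 0,0,-1),
  c(-1,0,0, 0,1,0, 0,0,-1)
)

# 432 generated by closure from the two cubic generators.
.make_rot_432 <- function() {
  g1 <- matrix(c(0,-1,0, 1,0,0, 0,0,1), 3, 3, byrow = TRUE)  # 4+ [001]
  g2 <- matrix(c(0,0,1, 1,0,0, 0,1,0), 3, 3, byrow = TRUE)   # 3+ [111]
  ops <- list(diag(3))
  key <- function(m) paste(as.integer(m), collapse = ",")
  seen <- key(diag(3))
  repeat {
    new <- list()
    for (a in ops) for (g in list(g1, g2)) {
      m <- a %*% g
      k <- key(m)
      if (!k %in% seen) { seen <- c(seen, k); new <- c(new, list(m)) }
    }
    if (!length(new)) break
    ops <- c(ops, new)
  }
  lapply(ops, function(R) list(R = R, t = c(0, 0, 0)))
}

# Screw translations for the four named groups (IT standard settings,
# verified against the published coordinate triplets).
.ops_with_t <- function(rots, ts) {
  stopifnot(length(rots) == length(ts))
  lapply(seq_along(rots), function(i) .op(rots[[i]], ts[[i]]))
}

.sg_table <- local({
  t0 <- c(0, 0, 0)
  # order matches .rot_422 above
  p41212 <- .ops_with_t(.rot_422, list(
    t0, c(0, 0, 1/2), c(1/2, 1/2, 1/4), c(1/2, 1/2, 3/4),
    c(1/2, 1/2, 1/4), c(1/2, 1/2, 3/4), t0, c(0, 0, 1/2)
  ))
  p4212 <- .ops_with_t(.rot_422, list(
    t0, t0, c(1/2, 1/2, 0), c(1/2, 1/2, 0),
    c(1/2, 1/2, 0), c(1/2, 1/2, 0), t0, t0
  ))
  p42212 <- .ops_with_t(.rot_422, list(
    t0, t0, c(1/2, 1/2, 1/2), c(1/2, 1/2, 1/2),
    c(1/2, 1/2, 1/2), c(1/2, 1/2, 1/2), t0, t0
  ))
  # order matches .rot_622 above
  p6522 <- .ops_with_t(.rot_622, list(
    t0, c(0, 0, 2/3), c(0, 0, 1/3), c(0, 0, 1/2), c(0, 0, 1/6), c(0, 0, 5/6),
    c(0, 0, 2/3), t0, c(0, 0, 1/3), c(0, 0, 1/6), c(0, 0, 1/2), c(0, 0, 5/6)
  ))
  plain <- function(rots) lapply(rots, .op)
  list(
    p41212 = list(symbol = "P41212", system = "tetragonal", operators = p41212,
                  conditions = list(h00 = 2L, `0k0` = 2L, `00l` = 4L)),
    p4212  = list(symbol = "P4212", system = "tetragonal", operators = p4212,
                  conditions = list(h00 = 2L, `0k0` = 2L)),
    p42212 = list(symbol = "P42212", system = "tetragonal", operators = p42212,
                  conditions = list(h00 = 2L, `0k0` = 2L, `00l` = 2L)),
    p6522  = list(symbol = "P6522", system = "hexagonal", operators = p6522,
                  conditions = list(`00l` = 6L)),
    `p-tetragonal`   = list(symbol = "P-tetragonal", system = "tetragonal",
                            operators = plain(.rot_422), conditions = list()),
    `p-hexagonal`    = list(symbol = "P-hexagonal", system = "hexagonal",
                            operators = plain(.rot_622), conditions = list()),
    `p-orthorhombic` = list(symbol = "P-orthorhombic", system = "orthorhombic",
                            operators = plain(.rot_222), conditions = list()),
    `p-cubic`        = list(symbol = "P-cubic", system = "cubic",
                            operators = .make_rot_432(), conditions = list())
  )
})

# ---- absences and equivalence ---------------------------------------------

#' Systematic absence of a reflection
#'
#' Applies the closed-form reflection conditions of the group's screw axes:
#' `h00`/`0k0` present only for even indices where a 2_1 axis runs along
#' a/b, and `00l` present only for l = 2n, 4n or 6n depending on the screw
#' component along c. General (hkl) reflections carry no condition in these
#' groups.
#'
#' @param rules A [space_group()].
#' @param hkl Length-3 integer vector or 3-column matrix.
#' @return Logical; `TRUE` when the reflection is forbidden.
#' @export
is_systematically_absent <- function(rules, hkl) {
  stopifnot(inherits(rules, "space_group"))
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  if (any(rowSums(m != 0) == 0)) stop("hkl = (0,0,0) is not a reflection", call. = FALSE)
  cond <- rules$conditions
  h <- m[, 1]; k <- m[, 2]; l <- m[, 3]
  out <- rep(FALSE, nrow(m))
  if (!is.null(cond$h00)) out <- out | (k == 0 & l == 0 & h %% cond$h00 != 0)
  if (!is.null(cond$`0k0`)) out <- out | (h == 0 & l == 0 & k %% cond$`0k0` != 0)
  if (!is.null(cond$`00l`)) out <- out | (h == 0 & k == 0 & l %% cond$`00l` != 0)
  out
}

# All symmetry-equivalent index triples of hkl (including Friedel mates),
# as a matrix of unique rows. h' = R^T h for each rotation part R.
equivalent_hkl <- function(rules, hkl) {
  h <- as.numeric(hkl)
  eq <- vapply(rules$operators, function(op) crossprod(op$R, h)[, 1], numeric(3))
  eq <- cbind(eq, -eq)
  uniq <- unique(t(round(eq)))
  storage.mode(uniq) <- "integer"
  uniq
}

# Canonical representative of the orbit: lexicographically greatest member.
canonical_hkl <- function(rules, hkl) {
  eq <- equivalent_hkl(rules, hkl)
  ord <- order(eq[, 1], eq[, 2], eq[, 3], decreasing = TRUE)
  eq[ord[1], ]
}

#' Reflection multiplicity
#'
#' Size of the orbit of `hkl` under the group's point symmetry plus Friedel
#' inversion — the number of lattice-plane orientations contributing to one
#' Debye–Scherrer ring.
#'
#' @inheritParams is_systematically_absent
#' @return Integer multiplicity, at least 2.
#' @export
reflection_multiplicity <- function(rules, hkl) {
  nrow(equivalent_hkl(rules, hkl))
}
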