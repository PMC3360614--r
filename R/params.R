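# Nearest-neighbor energy model, loaded from packaged TSV tables so that the
# parameter set can be swapped without touching any algorithm code. Stacks are
# Watson-Crick values after Xia et al. (1998) plus G.U values after Mathews et
# al. (1999), free energies at 37 C in kcal/mol. Loop penalties are
# length-dependent with logarithmic extrapolation beyond the tabulated sizes.

.mirest_env <- new.env(parent = emptyenv())

base_index <- function(b) match(b, c("A", "C", "G", "U")) - 1L

#' Load the packaged nearest-neighbor energy parameters
#'
#' Reads the stack, loop and constant tables shipped under `extdata` and
#' assembles the lookup structures used by the folding and duplex dynamic
#' programs. The result is cached for the session.
#'
#' @param stacks,loops,constants optional paths overriding the packaged
#'   tables (same TSV layouts).
#' @return a list with elements `stack` (length-625 lookup vector indexed by
#'   base codes of the two stacked pairs), `pair_ok` (5x5 logical), `hairpin`,
#'   `bulge`, `internal` (penalty-by-size vectors, kcal/mol), `duplex_init`
#'   and `max_interior`.
#' @export
energy_params <- function(stacks = NULL, loops = NULL, constants = NULL) {
  custom <- !is.null(stacks) || !is.null(loops) || !is.null(constants)
  if (!custom && !is.null(.mirest_env$params)) return(.mirest_env$params)
  path <- function(f) system.file("extdata", f, package = "mirest", mustWork = TRUE)
  st <- read.delim(stacks %||% path("nn_stacks.tsv"), stringsAsFactors = FALSE)
  lo <- read.delim(loops %||% path("nn_loops.tsv"), stringsAsFactors = FALSE)
  co <- read.delim(constants %||% path("nn_constants.tsv"), stringsAsFactors = FALSE)
  const <- setNames(co$value, co$name)
  lxc <- const[["loop_extrapolation"]]
  max_interior <- as.integer(const[["max_interior"]])

  stack <- rep(Inf, 5^4)
  idx <- function(x1, y1, x2, y2) (((x1 * 5 + y1) * 5 + x2) * 5 + y2) + 1L
  for (r in seq_len(nrow(st))) {
    stack[idx(base_index(st$pair1_x[r]), base_index(st$pair1_y[r]),
              base_index(st$pair2_x[r]), base_index(st$pair2_y[r]))] <- st$dg[r]
  }
  # antiparallel symmetry: 5'X1X2/3'Y1Y2 == 5'Y2Y1/3'X2X1
  for (r in seq_len(nrow(st))) {
    a <- st$dg[r]
    b <- stack[idx(base_index(st$pair2_y[r]), base_index(st$pair2_x[r]),
                   base_index(st$pair1_y[r]), base_index(st$pair1_x[r]))]
    if (!isTRUE(all.equal(a, b))) {
      stop("stack table is not antiparallel-symmetric; check nn_stacks.tsv")
    }
  }

  pair_ok <- matrix(FALSE, 5, 5)
  pairs <- rbind(c("A", "U"), c("U", "A"), c("C", "G"), c("G", "C"),
                 c("G", "U"), c("U", "G"))
  for (r in seq_len(nrow(pairs))) {
    pair_ok[base_index(pairs[r, 1]) + 1L, base_index(pairs[r, 2]) + 1L] <- TRUE
  }

  extrap <- function(tab, upto) {
    sizes <- tab$size
    v <- rep(Inf, upto)
    v[sizes] <- tab$dg
    mx <- max(sizes)
    if (upto > mx) {
      v[(mx + 1):upto] <- tab$dg[sizes == mx] + lxc * log((mx + 1):upto / mx)
    }
    v
  }
  hairpin_max <- 400L
  hp <- extrap(lo[lo$type == "hairpin", ], hairpin_max)
  if (any(is.finite(hp[seq_len(2)]))) stop("hairpin loops below 3 nt are disallowed")
  params <- list(
    stack = stack,
    pair_ok = pair_ok,
    hairpin = hp,
    bulge = extrap(lo[lo$type == "bulge", ], max_interior),
    internal = extrap(lo[lo$type == "internal", ], max_interior),
    duplex_init = const[["duplex_init"]],
    max_interior = max_interior
  )
  if (!custom) .mirest_env$params <- params
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stack_energy <- function(params, x1, y1, x2, y2) {
  params$stack[(((x1 * 5 + y1) * 5 + x2) * 5 + y2) + 1L]
}
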