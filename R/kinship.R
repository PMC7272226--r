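#' Pedigree kinship and inbreeding coefficients
#'
#' Recursive path-counting kinship on an explicit pedigree. The kinship
#' coefficient `phi(a, b)` is the probability that one allele sampled at
#' random from `a` and one from `b` are identical by descent; the
#' inbreeding coefficient of an individual equals the kinship of its
#' parents. Founders (unknown parents) are assumed unrelated and
#' non-inbred.
#'
#' The standard recursion is used: `phi(a, a) = (1 + F_a) / 2` with
#' `F_a = phi(father_a, mother_a)`, and for distinct individuals the later
#' born of the two is expanded through its parents,
#' `phi(a, b) = (phi(father_a, b) + phi(mother_a, b)) / 2`.
#'
#' @param pedigree Tibble/data frame with columns `id`, `father`, `mother`
#'   (`NA` for founders), ordered so that parents appear before their
#'   offspring.
#' @param id1,id2 Individual ids.
#' @return Kinship coefficient in \[0, 0.5 * (1 + F)\].
#' @export
#' @examples
#' ped <- cousin_pedigree(degree = 2)
#' inbreeding_coefficient(ped, "child")  # 1/64 for second-cousin parents
kinship_coefficient <- function(pedigree, id1, id2) {
  ped <- .check_pedigree(pedigree)
  ord <- stats::setNames(seq_len(nrow(ped)), ped$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (ord[[a]] <= ord[[b]]) paste(a, b) else paste(b, a)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(ped$father[ord[[a]]], ped$mother[ord[[a]]]))
    } else {
      # expand the individual that appears later in the pedigree
      if (ord[[a]] < ord[[b]]) { tmp <- a; a <- b; b <- tmp }
      i <- ord[[a]]
      0.5 * (phi(ped$father[i], b) + phi(ped$mother[i], b))
    }
    memo[[key]] <- val
    val
  }
  phi(id1, id2)
}

#' @rdname kinship_coefficient
#' @param id Individual whose inbreeding coefficient is wanted.
#' @export
inbreeding_coefficient <- function(pedigree, id) {
  ped <- .check_pedigree(pedigree)
  i <- match(id, ped$id)
  if (is.na(i)) stop("unknown id: ", id, call. = FALSE)
  f <- ped$father[i]
  m <- ped$mother[i]
  if (is.na(f) || is.na(m)) return(0)
  kinship_coefficient(ped, f, m)
}

.check_pedigree <- function(pedigree) {
  req <- c("id", "father", "mother")
  if (!all(req %in% names(pedigree))) {
    stop("pedigree needs columns id, father, mother", call. = FALSE)
  }
  if (anyDuplicated(pedigree$id)) stop("duplicated pedigree ids",
                                       call. = FALSE)
  for (col in c("father", "mother")) {
    par <- pedigree[[col]]
    known <- !is.na(par)
    pidx <- match(par[known], pedigree$id)
    if (anyNA(pidx)) stop("parent not in pedigree: ",
                          par[known][is.na(pidx)][1], call. = FALSE)
    if (any(pidx >= which(known))) {
      stop("pedigree must list parents before offspring", call. = FALSE)
    }
  }
  pedigree
}

#' Pedigree for offspring of n-th-degree cousins
#'
#' Builds the minimal pedigree in which two mates are first, second, ...
#' cousins (sharing one ancestral couple `degree` generations above their
#' parents) and returns it with a terminal individual `"child"`. The
#' child's inbreeding coefficient is `1 / 4^(degree + 1)`: 1/16 for first
#' cousins, 1/64 for second cousins.
#'
#' @param degree Cousin degree (1 = first cousins).
#' @return Pedigree tibble usable with [inbreeding_coefficient()].
#' @export
cousin_pedigree <- function(degree = 2) {
  stopifnot(degree >= 1)
  rows <- list(
    c("anc_f", NA, NA),
    c("anc_m", NA, NA),
    c("L0", "anc_f", "anc_m"),
    c("R0", "anc_f", "anc_m")
  )
  for (g in seq_len(degree)) {
    rows <- c(rows, list(
      c(sprintf("L%d_sp", g - 1), NA, NA),
      c(sprintf("R%d_sp", g - 1), NA, NA),
      c(sprintf("L%d", g), sprintf("L%d", g - 1), sprintf("L%d_sp", g - 1)),
      c(sprintf("R%d", g), sprintf("R%d", g - 1), sprintf("R%d_sp", g - 1))
    ))
  }
  rows <- c(rows, list(c("child", sprintf("L%d", degree),
                         sprintf("R%d", degree))))
  m <- do.call(rbind, rows)
  tibble::tibble(id = m[, 1], father = m[, 2], mother = m[, 3])
}
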