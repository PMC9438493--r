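#' SpaceGroupSpec: symmetry operators and origin conventions
#'
#' A space group is represented by its full list of symmetry operators
#' (integer 3x3 rotation part, fractional translation part), together with
#' the bookkeeping needed for ab initio phasing: whether the group is one of
#' the 22 chiral groups (where inverting the density changes the group, so
#' no inversion ambiguity arises within the group), the enantiomorphic
#' partner where one exists, and the set of permitted origin shifts --
#' the translations that leave the group's operators invariant, under which
#' the amplitude data cannot distinguish two otherwise identical solutions.
#'
#' @slot name text label, e.g. "P212121"
#' @slot ops list of operators, each `list(R = <3x3 integer matrix>, t = <fractional translation>)`
#' @slot chiral TRUE for the 22 chiral groups (enantiomorphic pairs)
#' @slot inversionAmbiguous TRUE when the inverted density satisfies the same
#'   group, so solutions may emerge with either hand
#' @slot originShifts matrix (n x 3) of permitted discrete fractional origin
#'   shifts (components along continuous axes set to 0)
#' @slot continuousAxes logical(3); TRUE where the origin floats continuously
#'   (polar directions)
#' @slot enantiomorphPartner name of the partner group, or NA
#' @name SpaceGroupSpec-class
#' @aliases SpaceGroupSpec
#' @exportClass SpaceGroupSpec
setClass("SpaceGroupSpec",
  representation(name = "character", ops = "list", chiral = "logical",
                 inversionAmbiguous = "logical", originShifts = "matrix",
                 continuousAxes = "logical",
                 enantiomorphPartner = "character"))

# --- symmetry-operator parsing -------------------------------------------

# parse one coordinate expression like "-x+y", "y+1/2", "z-1/6"
.parseCoordExpr <- function(txt) {
  txt <- gsub("[[:space:]]", "", tolower(txt))
  row <- c(0, 0, 0); tr <- 0
  # tokenize into signed terms
  terms <- regmatches(txt, gregexpr("[+-]?[^+-]+", txt))[[1]]
  for (tm in terms) {
    sgn <- if (startsWith(tm, "-")) -1 else 1
    body <- sub("^[+-]", "", tm)
    if (body %in% c("x", "y", "z")) {
      row[match(body, c("x", "y", "z"))] <- row[match(body, c("x", "y", "z"))] + sgn
    } else if (grepl("^[0-9]+/[0-9]+$", body)) {
      fr <- as.numeric(strsplit(body, "/")[[1]])
      tr <- tr + sgn * fr[1] / fr[2]
    } else if (grepl("^[0-9.]+$", body)) {
      tr <- tr + sgn * as.numeric(body)
    } else {
      .stopf("cannot parse symmetry-operator term '%s'", tm)
    }
  }
  list(row = row, t = tr %% 1)
}

#' Parse a symmetry operator in triplet notation
#' @param txt e.g. `"-x, y+1/2, -z"`
#' @return `list(R = <3x3 matrix>, t = <numeric(3)>)`
#' @export
parseSymop <- function(txt) {
  parts <- strsplit(txt, ",")[[1]]
  if (length(parts) != 3) .stopf("operator '%s' does not have three components", txt)
  pp <- lapply(parts, .parseCoordExpr)
  list(R = do.call(rbind, lapply(pp, `[[`, "row")),
       t = vapply(pp, `[[`, numeric(1), "t"))
}

.opsFromStrings <- function(strs) lapply(strs, parseSymop)

.opKey <- function(op) paste(c(op$R, round(op$t * 24) %% 24), collapse = " ")

.composeOps <- function(g, h) {
  # (g*h)(x) = g(h(x))
  list(R = g$R %*% h$R, t = as.numeric(g$R %*% h$t + g$t) %% 1)
}

.invertOp <- function(g) {
  Ri <- solve(g$R)
  list(R = round(Ri), t = (-as.numeric(Ri %*% g$t)) %% 1)
}

.checkGroupClosure <- function(ops) {
  keys <- vapply(ops, .opKey, character(1))
  if (anyDuplicated(keys)) return("duplicate symmetry operators")
  idKey <- .opKey(list(R = diag(3), t = c(0, 0, 0)))
  if (!idKey %in% keys) return("identity operator missing")
  for (g in ops) for (h in ops) {
    if (!.opKey(.composeOps(g, h)) %in% keys)
      return("operator list is not closed under composition")
  }
  TRUE
}

setValidity("SpaceGroupSpec", function(object) {
  cl <- .checkGroupClosure(object@ops)
  if (!isTRUE(cl)) return(cl)
  if (ncol(object@originShifts) != 3) return("originShifts must have 3 columns")
  if (length(object@continuousAxes) != 3) return("continuousAxes must be logical(3)")
  if (object@chiral && object@inversionAmbiguous)
    return("a chiral group cannot be inversion-ambiguous (inversion changes the group)")
  TRUE
})

# --- built-in table -------------------------------------------------------

.builtinSG <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    half <- c(0, 0.5)
    mk <- function(name, strs, chiral, invAmb, shifts, contin, partner = NA_character_) {
      new("SpaceGroupSpec", name = name, ops = .opsFromStrings(strs),
          chiral = chiral, inversionAmbiguous = invAmb,
          originShifts = shifts, continuousAxes = contin,
          enantiomorphPartner = partner)
    }
    g8 <- as.matrix(expand.grid(half, half, half))
    dimnames(g8) <- NULL
    tbl <<- list(
      P1 = mk("P1", "x,y,z", FALSE, TRUE,
              matrix(0, 1, 3), c(TRUE, TRUE, TRUE)),
      P21 = mk("P21", c("x,y,z", "-x,y+1/2,-z"), FALSE, TRUE,
               {m <- as.matrix(expand.grid(half, 0, half)); dimnames(m) <- NULL; m},
               c(FALSE, TRUE, FALSE)),
      P212121 = mk("P212121",
                   c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                     "x+1/2,-y+1/2,-z"),
                   FALSE, TRUE, g8, c(FALSE, FALSE, FALSE)),
      I222 = mk("I222",
                c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                  "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
                  "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2"),
                FALSE, TRUE, g8, c(FALSE, FALSE, FALSE)),
      P61 = mk("P61",
               c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3", "-x,-y,z+1/2",
                 "y,-x+y,z+5/6", "x-y,x,z+1/6"),
               TRUE, FALSE, matrix(0, 1, 3), c(FALSE, FALSE, TRUE), "P65"),
      P65 = mk("P65",
               c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3", "-x,-y,z+1/2",
                 "y,-x+y,z+1/6", "x-y,x,z+5/6"),
               TRUE, FALSE, matrix(0, 1, 3), c(FALSE, FALSE, TRUE), "P61")
    )
    tbl
  }
})

.sgAlias <- function(name) {
  key <- toupper(gsub("[[:space:]()_]", "", name))
  map <- c("P1" = "P1", "P21" = "P21", "P1211" = "P21",
           "P212121" = "P212121", "I222" = "I222",
           "P61" = "P61", "P65" = "P65")
  unname(map[key])
}

#' Look up a built-in space group
#'
#' The built-in table covers P1, P21, P212121, I222 and the enantiomorphic
#' pair P61/P65. Other groups can be supplied via [spaceGroupFromOps()] or
#' [readSymmetryOps()].
#' @param name space-group symbol, e.g. `"P212121"` or `"P 21 21 21"`
#' @return a [SpaceGroupSpec-class]
#' @export
spaceGroup <- function(name) {
  if (is(name, "SpaceGroupSpec")) return(name)
  key <- .sgAlias(name)
  if (is.na(key)) .stopf("space group '%s' is not in the built-in table", name)
  .builtinSG()[[key]]
}

#' Build a space group from user-supplied operators
#'
#' For groups outside the built-in table. Origin-shift and hand conventions
#' must then be supplied by the caller; by default the group is treated as
#' having discrete origin shifts at all half-cell translations that commute
#' with its operators.
#'
#' @param name label
#' @param ops character vector of triplet operators, or a list of
#'   `list(R, t)` pairs
#' @param chiral is this one of the 22 chiral groups?
#' @param originShifts n x 3 matrix of permitted shifts; if NULL, computed by
#'   testing which translations with denominators up to 6 leave every operator
#'   invariant
#' @param continuousAxes logical(3); if NULL, detected from the operators
#'   (an axis is polar when every rotation part fixes it)
#' @param enantiomorphPartner optional partner name
#' @export
spaceGroupFromOps <- function(name, ops, chiral = FALSE,
                              originShifts = NULL, continuousAxes = NULL,
                              enantiomorphPartner = NA_character_) {
  if (is.character(ops)) ops <- .opsFromStrings(ops)
  if (is.null(continuousAxes)) {
    # axis j is continuous iff (R - I) annihilates e_j for every op
    continuousAxes <- vapply(1:3, function(j) {
      all(vapply(ops, function(g) all((g$R - diag(3))[, j] == 0), logical(1)))
    }, logical(1))
  }
  if (is.null(originShifts)) {
    cand <- as.matrix(expand.grid(0:5 / 6, 0:5 / 6, 0:5 / 6))
    ok <- apply(cand, 1, function(tv) {
      if (any(tv[continuousAxes] != 0)) return(FALSE)
      all(vapply(ops, function(g) {
        d <- as.numeric((g$R - diag(3)) %*% tv)
        all(abs(d - round(d)) < 1e-9)
      }, logical(1)))
    })
    originShifts <- cand[ok, , drop = FALSE]
    dimnames(originShifts) <- NULL
  }
  new("SpaceGroupSpec", name = name, ops = ops, chiral = chiral,
      inversionAmbiguous = !chiral, originShifts = originShifts,
      continuousAxes = continuousAxes,
      enantiomorphPartner = enantiomorphPartner)
}

#' Read symmetry operators from a text file (one triplet per line)
#' @param path file with lines like `-x, y+1/2, -z`; `#` comments allowed
#' @param name label for the resulting group
#' @param ... passed to [spaceGroupFromOps()]
#' @export
readSymmetryOps <- function(path, name = basename(path), ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  spaceGroupFromOps(name, lines, ...)
}

#' Number of symmetry operators
#' @param sg a [SpaceGroupSpec-class]
#' @export
nSymops <- function(sg) length(sg@ops)

#' @describeIn SpaceGroupSpec-class permitted origin shifts (matrix n x 3)
#' @param sg a \code{SpaceGroupSpec}
#' @export
originShifts <- function(sg) sg@originShifts

#' @describeIn SpaceGroupSpec-class logical(3): axes with continuous origin
#' @export
continuousOriginAxes <- function(sg) sg@continuousAxes

#' @describeIn SpaceGroupSpec-class is the inverted density a valid solution
#'   in the same group?
#' @export
inversionAmbiguous <- function(sg) sg@inversionAmbiguous

setMethod("show", "SpaceGroupSpec", function(object) {
  cat(sprintf("SpaceGroupSpec %s: %d operator(s); %s; origin shifts: %d discrete%s%s\n",
              object@name, length(object@ops),
              if (object@chiral) "chiral" else "achiral (inversion-ambiguous)",
              nrow(object@originShifts),
              if (any(object@continuousAxes))
                paste0(", continuous along ",
                       paste(c("a", "b", "c")[object@continuousAxes], collapse = ",")) else "",
              if (!is.na(object@enantiomorphPartner))
                paste0("; enantiomorph ", object@enantiomorphPartner) else ""))
})

# --- reflection classification -------------------------------------------

#' Reduce Miller indices to symmetry-unique representatives
#'
#' Each reflection orbit under the Laue group (rotations plus the Friedel
#' mate) is represented by its lexicographically greatest member. Also
#' reports the centric flag (phase restricted to two values), the symmetry
#' enhancement factor epsilon, and -- when `details = TRUE` -- the relation
#' needed to carry a phase from the representative to the input index.
#'
#' @param hkl n x 3 integer matrix
#' @param sg a [SpaceGroupSpec-class]
#' @param details also return conjugation flags and phase shifts
#' @return data.frame with columns h,k,l (canonical), centric, epsilon and,
#'   with details, conj (logical) and phaseShiftDeg such that
#'   `phi(input) = conj ? -(phi(canon) + shift) : phi(canon) + shift`
#' @export
canonicalHKL <- function(hkl, sg, details = FALSE) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  n <- nrow(hkl)
  ops <- sg@ops
  nop <- length(ops)
  # candidates: for each op g, +/- R_g^T h
  best <- hkl
  bestOp <- rep(1L, n); bestSign <- rep(1L, n)
  first <- TRUE
  for (gi in seq_len(nop)) {
    Rt <- t(ops[[gi]]$R)
    for (sgn in c(1L, -1L)) {
      cand <- sgn * (hkl %*% t(Rt))   # rows: (R^T h)^T
      if (first) {
        best <- cand; bestOp <- rep(gi, n); bestSign <- rep(sgn, n)
        first <- FALSE
      } else {
        better <- (cand[, 1] > best[, 1]) |
          (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
          (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
        if (any(better)) {
          best[better, ] <- cand[better, , drop = FALSE]
          bestOp[better] <- gi; bestSign[better] <- sgn
        }
      }
    }
  }
  eps <- integer(n); centr <- logical(n)
  for (gi in seq_len(nop)) {
    Rt <- t(ops[[gi]]$R)
    img <- best %*% t(Rt)
    eps <- eps + as.integer(rowSums(img == best) == 3L)
    centr <- centr | (rowSums(img == -best) == 3L)
  }
  out <- data.frame(h = best[, 1], k = best[, 2], l = best[, 3],
                    centric = centr, epsilon = eps)
  if (details) {
    # input h_in relates to canonical h_u via h_in = sign * R_{g^-1}^T h_u
    invT <- lapply(ops, function(g) .invertOp(g)$t)
    shift <- numeric(n); cj <- logical(n)
    for (gi in seq_len(nop)) {
      sel <- bestOp == gi
      if (!any(sel)) next
      tv <- invT[[gi]]
      shift[sel] <- -360 * (best[sel, , drop = FALSE] %*% tv)
      cj[sel] <- bestSign[sel] == -1L
    }
    out$conj <- cj
    out$phaseShiftDeg <- .wrap360(shift)
  }
  out
}

#' Centric phase restriction
#'
#' For a centric reflection the phase is restricted to one of two values
#' 180 degrees apart; this returns the smaller allowed value in degrees.
#' @param hkl n x 3 matrix of canonical Miller indices
#' @param sg a [SpaceGroupSpec-class]
#' @return numeric vector; NA for acentric reflections
#' @export
centricPhaseRestriction <- function(hkl, sg) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  out <- rep(NA_real_, nrow(hkl))
  for (g in sg@ops) {
    img <- hkl %*% g$R  # rows: (R^T h)^T
    sel <- rowSums(img == -hkl) == 3L & is.na(out)
    if (any(sel))
      out[sel] <- (180 * (hkl[sel, , drop = FALSE] %*% g$t)) %% 180
  }
  out
}

# --- symmetry on grids ----------------------------------------------------

# check that every operator maps the grid onto itself
.gridCompatible <- function(sg, dims) {
  for (g in sg@ops) {
    tn <- g$t * dims
    if (any(abs(tn - round(tn)) > 1e-9)) return(FALSE)
    for (a in 1:3) for (b in 1:3) {
      if (g$R[a, b] != 0 && (dims[a] * abs(g$R[a, b])) %% dims[b] != 0)
        return(FALSE)
    }
  }
  TRUE
}

.permCache <- new.env(parent = emptyenv())

# permutation p with p[i] = linear index of g(x_i); rho_sym = mean_g rho[p_g]
.opPermutations <- function(sg, dims) {
  key <- paste(sg@name, paste(dims, collapse = "x"),
               paste(vapply(sg@ops, .opKey, character(1)), collapse = "|"))
  hit <- .permCache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- .gridIndex0(dims)
  perms <- lapply(sg@ops, function(g) {
    j <- vector("list", 3)
    for (a in 1:3) {
      acc <- round(g$t[a] * dims[a])
      for (b in 1:3) {
        if (g$R[a, b] != 0) {
          fac <- g$R[a, b] * dims[a] / dims[b]  # integer by compatibility
          acc <- acc + fac * idx[[b]]
        }
      }
      j[[a]] <- acc %% dims[a]
    }
    as.integer(1 + j[[1]] + dims[1] * (j[[2]] + dims[2] * j[[3]]))
  })
  .permCache[[key]] <- perms
  perms
}

# average a numeric array over the group (makes it symmetry-consistent)
.symmetrizeValues <- function(vals, sg, dims) {
  if (length(sg@ops) == 1L) return(vals)
  perms <- .opPermutations(sg, dims)
  acc <- numeric(length(vals))
  for (p in perms) acc <- acc + vals[p]
  array(acc / length(perms), dim = dims)
}
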