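# Internal-coordinate geometry: Z-matrix atom placement (NeRF), ideal
# hydrogen building, and template-based side-chain construction.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Torsion angle p1-p2-p3-p4 in degrees, IUPAC sign convention.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom D bonded to C with |DC| = b, angle D-C-B = a (deg) and
# torsion D-C-B-A = t (deg).
place_zmat_atom <- function(C, B, A, b, a, t) {
  a <- a * pi / 180; t <- t * pi / 180
  u <- unitv(C - B)
  n <- cross3(B - A, u)
  if (vnorm(n) < 1e-8) n <- cross3(c(1, 0, 0), u)
  if (vnorm(n) < 1e-8) n <- cross3(c(0, 1, 0), u)
  n <- unitv(n)
  m <- cross3(n, u)
  C + b * (cos(a) * u + sin(a) * (cos(t) * m + sin(t) * n))
}

# Heavy neighbours of an atom within a residue template (plus the
# peptide-bond C of the previous residue for backbone N).
heavy_neighbors <- function(tpl, atom) {
  pairs <- strsplit(tpl$bonds, " ", fixed = TRUE)
  nb <- character()
  for (p in pairs) {
    if (p[1] == atom) nb <- c(nb, p[2])
    if (p[2] == atom) nb <- c(nb, p[1])
  }
  nb[!startsWith(nb, "H") & !grepl("^[0-9]*H", nb)]
}

element_of <- function(name) {
  if (grepl("^[0-9]*H", name)) "H" else substr(name, 1, 1)
}

# Build all template hydrogens missing from one residue.  `res` is an
# atom-table subset for the residue; `prev_C` the coordinates of the
# preceding residue's carbonyl C (or NULL).  Returns a data frame of
# new hydrogen rows (name, x, y, z).
build_res_hydrogens <- function(res, tpl, prev_C = NULL,
                                nter = FALSE) {
  pos <- function(nm) {
    i <- match(nm, res$atom_name)
    if (is.na(i)) return(NULL)
    c(res$x[i], res$y[i], res$z[i])
  }
  hmap <- tpl$hydrogens
  if (nter) {
    # NH3+ terminus: replace the single backbone HN by HT1..HT3
    hmap <- hmap[names(hmap) != "HN"]
    if ("N" %in% res$atom_name && !("CD" %in% heavy_neighbors(tpl, "N")))
      hmap <- c(hmap, HT1 = "N", HT2 = "N", HT3 = "N")
  }
  missing <- setdiff(names(hmap), res$atom_name)
  if (!length(missing)) return(NULL)
  out <- list()
  for (parent in unique(unname(hmap[missing]))) {
    hs <- missing[hmap[missing] == parent]
    P <- pos(parent)
    if (is.null(P)) next
    pel <- element_of(parent)
    blen <- H_BOND_LENGTH[[pel]]
    nbn <- heavy_neighbors(tpl, parent)
    if (parent == "N" && !is.null(prev_C) && !nter)
      nbpos <- c(lapply(nbn, pos), list(prev_C))
    else
      nbpos <- lapply(nbn, pos)
    nbpos <- Filter(Negate(is.null), nbpos)
    nh_total <- sum(hmap == parent)
    sp2 <- parent %in% tpl$sp2
    newpos <- place_hydrogens(P, nbpos, nbn, hs, nh_total, sp2, blen,
                              pel, tpl, pos)
    for (i in seq_along(hs))
      out[[length(out) + 1]] <- data.frame(name = hs[i],
                                           x = newpos[[i]][1],
                                           y = newpos[[i]][2],
                                           z = newpos[[i]][3])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

place_hydrogens <- function(P, nbpos, nbn, hs, nh, sp2, blen, pel,
                            tpl, pos) {
  nn <- length(nbpos)
  k <- length(hs)  # hydrogens still to place
  res <- vector("list", k)
  if (nn == 0) {
    # free molecule (water): deterministic local frame
    res[[1]] <- P + blen * c(1, 0, 0)
    if (k > 1)
      res[[2]] <- P + blen * c(cos(104.52 * pi / 180),
                               sin(104.52 * pi / 180), 0)
    return(res)
  }
  us <- lapply(nbpos, function(q) unitv(q - P))
  if (nn >= 3) {
    d <- -unitv(Reduce(`+`, us))
    res[[1]] <- P + blen * d
    return(res)
  }
  if (nn == 2) {
    bis <- -(us[[1]] + us[[2]])
    if (vnorm(bis) < 1e-8) bis <- cross3(us[[1]], c(0, 0, 1))
    bis <- unitv(bis)
    if (k == 1) {
      res[[1]] <- P + blen * bis
    } else {
      perp <- unitv(cross3(us[[1]], us[[2]]))
      half <- 0.5 * 109.47 * pi / 180
      res[[1]] <- P + blen * (cos(half) * bis + sin(half) * perp)
      res[[2]] <- P + blen * (cos(half) * bis - sin(half) * perp)
    }
    return(res)
  }
  # nn == 1: need a reference third atom through the neighbour
  Q <- nbpos[[1]]
  refpos <- NULL
  qn <- heavy_neighbors(tpl, nbn[1])
  for (r in setdiff(qn, character(0))) {
    rp <- pos(r)
    if (!is.null(rp) && vnorm(rp - P) > 1e-6) { refpos <- rp; break }
  }
  if (is.null(refpos)) refpos <- Q + c(0, 0, 1)
  ang <- if (sp2) 120 else if (pel == "S") 96 else
    if (pel == "O") 108.5 else 109.5
  tors <- if (sp2) c(180, 0) else c(180, 60, -60)
  for (i in seq_len(k))
    res[[i]] <- place_zmat_atom(P, Q, refpos, blen, ang, tors[i])
  res
}

# Build side-chain heavy atoms for a residue from the template Z-matrix,
# keeping any that already exist.  `res` must contain backbone N, CA, C.
build_sidechain_heavy <- function(res, tpl) {
  known <- setNames(lapply(seq_len(nrow(res)),
                           function(i) c(res$x[i], res$y[i], res$z[i])),
                    res$atom_name)
  added <- list()
  for (row in tpl$zmat) {
    if (row$atom %in% names(known)) next
    refs <- list(known[[row$r1]], known[[row$r2]], known[[row$r3]])
    if (any(vapply(refs, is.null, TRUE)))
      stop("cannot place ", row$atom, ": missing reference atoms")
    p <- place_zmat_atom(refs[[1]], refs[[2]], refs[[3]],
                         row$b, row$a, row$t)
    known[[row$atom]] <- p
    added[[length(added) + 1]] <- data.frame(name = row$atom,
                                             x = p[1], y = p[2],
                                             z = p[3])
  }
  if (!length(added)) return(NULL)
  do.call(rbind, added)
}
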