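## structure_prep: common-substructure superposition onto the template.
##
## Every compound is rigidly superimposed onto the template conformer
## (the most active analogue, compound 10) by least-squares fitting of the
## heavy atoms of the shared (Z)-N-benzylidenebenzenamine fragment (two
## phenyl rings joined by CH=N; 14 heavy atoms).

.elementColor <- function(el) {
  lv <- c("H", "C", "N", "O", "S", "Br")
  i <- match(el, lv)
  if (anyNA(i)) i[is.na(i)] <- length(lv) + match(el[is.na(i)], unique(el[is.na(i)]))
  as.integer(i)
}

# heavy-atom connectivity graph with element colors
.heavyGraph <- function(conf) {
  a <- conf@atoms
  heavy <- which(a$element != "H")
  idx <- match(seq_len(nrow(a)), heavy)  # atom -> heavy index
  b <- conf@bonds
  keep <- a$element[b[, "from"]] != "H" & a$element[b[, "to"]] != "H"
  el <- cbind(idx[b[keep, "from"]], idx[b[keep, "to"]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$color <- .elementColor(a$element[heavy])
  list(graph = g, heavy = heavy)
}

#' The benzylideneaniline alignment fragment
#'
#' Topology of the 14-heavy-atom (Z)-N-benzylidenebenzenamine fragment
#' (phenyl-CH=N-phenyl) shared by all compounds of the series and used as the
#' common substructure for superposition.
#'
#' @return an igraph graph with a \code{color} vertex attribute encoding the
#'   element (vertex 1 = N, vertex 2 = azomethine C, 3-8 = C ring attached at
#'   C, 9-14 = C ring attached at N).
#' @export
benzylideneFragment <- function() {
  # 1 N, 2 C(H)=N; 3..8 phenyl on C2; 9..14 phenyl on N1
  edges <- rbind(c(1, 2), c(2, 3),
    c(3, 4), c(4, 5), c(5, 6), c(6, 7), c(7, 8), c(8, 3),
    c(1, 9),
    c(9, 10), c(10, 11), c(11, 12), c(12, 13), c(13, 14), c(14, 9))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$color <- .elementColor(c("N", rep("C", 13)))
  g
}

# all substructure matches of the fragment in a conformer, as matrices of
# atom indices (rows = matches, in deterministic lexicographic order)
.fragmentMatches <- function(conf, fragment) {
  hg <- .heavyGraph(conf)
  iso <- igraph::subgraph_isomorphisms(fragment, hg$graph, method = "vf2")
  if (!length(iso))
    stop("alignment fragment not found in compound ", conf@compoundId)
  m <- t(vapply(iso, function(mp) hg$heavy[as.integer(mp)],
                integer(igraph::vcount(fragment))))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' \code{P \%*\% t(R) + t} against \code{Q} over paired rows.
#'
#' @param P,Q numeric n x 3 coordinate matrices (moving and reference).
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3), \code{rmsd}.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  list(rotation = R, translation = as.numeric(qc - pc %*% t(R)), rmsd = rmsd)
}

#' Superimpose a conformer onto a template via the common substructure
#'
#' Enumerates all substructure matches of the fragment in the target (the
#' fragment is symmetric across its phenyl rings, so several matches exist),
#' performs a Kabsch superposition for each against the template's matched
#' heavy atoms, and keeps the match of lowest RMSD (ties resolved to the
#' lowest atom-index order). Hydrogens are excluded from the fit.
#'
#' @param target,template \code{\link{Conformer}} objects.
#' @param fragment substructure pattern, as from
#'   \code{\link{benzylideneFragment}}.
#' @return list with \code{conformer} (the target with transformed
#'   coordinates) and \code{result}: rotation (proper, det +1), translation,
#'   rmsd over matched heavy atoms, and \code{matchedPairs}
#'   (template atom index, target atom index).
#' @export
alignToTemplate <- function(target, template, fragment = benzylideneFragment()) {
  tmplMatch <- .fragmentMatches(template, fragment)[1, ]
  Q <- atomCoords(template)[tmplMatch, , drop = FALSE]
  cand <- .fragmentMatches(target, fragment)
  fits <- lapply(seq_len(nrow(cand)), function(i)
    kabsch(atomCoords(target)[cand[i, ], , drop = FALSE], Q))
  rmsds <- vapply(fits, `[[`, 0, "rmsd")
  best <- which.min(rmsds)  # ties: which.min takes the first = lowest index order
  fit <- fits[[best]]
  xyz <- atomCoords(target) %*% t(fit$rotation) +
    matrix(fit$translation, nAtoms(target), 3, byrow = TRUE)
  aligned <- target
  atomCoords(aligned) <- xyz
  list(conformer = aligned,
       result = list(rotation = fit$rotation, translation = fit$translation,
                     rmsd = fit$rmsd,
                     matchedPairs = cbind(template = tmplMatch,
                                          target = cand[best, ])))
}

#' Align a conformer set onto a template
#'
#' @param confs list of \code{\link{Conformer}} objects.
#' @param templateId id of the template compound (default \code{"10"}, the
#'   most active analogue of the packaged series).
#' @param fragment substructure pattern.
#' @return list with \code{conformers} (aligned set, template included
#'   unchanged) and \code{results} (per-compound alignment records).
#' @export
alignSet <- function(confs, templateId = "10",
                     fragment = benzylideneFragment()) {
  if (!templateId %in% names(confs))
    stop("template id ", templateId, " not in conformer set")
  template <- confs[[templateId]]
  out <- lapply(names(confs), function(id) {
    if (id == templateId)
      list(conformer = template,
           result = list(rotation = diag(3), translation = numeric(3),
                         rmsd = 0, matchedPairs = NULL))
    else alignToTemplate(confs[[id]], template, fragment)
  })
  list(conformers = stats::setNames(lapply(out, `[[`, "conformer"),
                                    names(confs)),
       results = stats::setNames(lapply(out, `[[`, "result"), names(confs)))
}

#' Write alignment transforms to a JSON sidecar
#' @param results the \code{results} element of \code{\link{alignSet}}.
#' @param path output JSON file.
#' @export
writeAlignmentJSON <- function(results, path) {
  jsonlite::write_json(lapply(results, function(r)
    list(rotation = r$rotation, translation = r$translation, rmsd = r$rmsd)),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
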