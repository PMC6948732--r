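#' Read a MetabolicNetwork from JSON
#'
#' Schema:
#' `{"metabolites":[{"id","ubiquitous"}],
#'   "reactions":[{"id","substrates":[],"products":[],"genes":[]}]}`.
#' Reversible reactions must be written as explicit directed duplicates.
#'
#' @param path JSON path.
#' @return a [MetabolicNetwork-class]
#' @export
readMetabolicNetwork <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$metabolites) || is.null(j$reactions))
    stop("network JSON needs 'metabolites' and 'reactions'")
  met <- data.frame(
    id = vapply(j$metabolites, function(m) as.character(m$id), character(1)),
    ubiquitous = vapply(j$metabolites, function(m) isTRUE(m$ubiquitous),
                        logical(1)),
    stringsAsFactors = FALSE)
  rxn <- lapply(j$reactions, function(r)
    list(id = r$id, substrates = unlist(r$substrates),
         products = unlist(r$products), genes = unlist(r$genes)))
  MetabolicNetwork(rxn, met)
}

#' Write a MetabolicNetwork to JSON
#' @param net a [MetabolicNetwork-class]
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMetabolicNetwork <- function(net, path) {
  j <- list(
    metabolites = lapply(seq_len(nrow(net@metabolites)), function(i)
      list(id = net@metabolites$id[i],
           ubiquitous = net@metabolites$ubiquitous[i])),
    reactions = lapply(unname(net@reactions), function(r)
      list(id = r$id, substrates = as.list(r$substrates),
           products = as.list(r$products), genes = as.list(r$genes))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Build a reaction-adjacency graph from a metabolic network
#'
#' Ubiquitous metabolites (water-like compounds and co-factors that would
#' over-connect the graph) are excluded from edge formation; for every
#' remaining metabolite, each producing reaction gains a directed edge to
#' each consuming reaction (no self-edges). Gene annotations are carried as
#' vertex attributes.
#'
#' @param net a [MetabolicNetwork-class]
#' @param extraUbiquitous additional metabolite ids to exclude.
#' @return a [ReactionGraph-class]
#' @export
buildReactionGraph <- function(net, extraUbiquitous = character()) {
  stopifnot(is(net, "MetabolicNetwork"))
  ubiq <- union(net@metabolites$id[net@metabolites$ubiquitous],
                extraUbiquitous)
  rids <- names(net@reactions)
  from <- character(); to <- character(); via <- character()
  for (m in setdiff(net@metabolites$id, ubiq)) {
    producers <- rids[vapply(net@reactions, function(r)
      m %in% r$products, logical(1))]
    consumers <- rids[vapply(net@reactions, function(r)
      m %in% r$substrates, logical(1))]
    for (p in producers) for (q in consumers) if (p != q) {
      from <- c(from, p); to <- c(to, q); via <- c(via, m)
    }
  }
  ed <- unique(data.frame(from = from, to = to,
                          stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = rids))
  igraph::V(g)$genes <- lapply(net@reactions[igraph::V(g)$name],
                               function(r) r$genes)
  if (nrow(ed)) {
    key <- paste(from, to)
    edKey <- paste(ed$from, ed$to)
    igraph::E(g)$via <- vapply(edKey, function(k)
      paste(unique(via[key == k]), collapse = ","), character(1))
  }
  methods::new("ReactionGraph", graph = g, groups = character())
}

#' Weight reaction-graph edges by adjacent pairwise expression correlation
#'
#' For each sample group and each edge r1 -> r2, the weight is the maximum
#' Pearson correlation over all gene pairs (gene of r1) x (gene of r2),
#' computed on that group's samples (`aggregate = "mean"` averages instead).
#' Edges where either reaction has no measured gene receive the group's
#' median edge weight and an `unmeasured_<group>` flag, preserving
#' connectivity.
#'
#' @param rg a [ReactionGraph-class]
#' @param expr a [FeatureMatrix-class] of expression, rows = gene ids.
#' @param groups character: groups to weight for; default all groups in
#'   `expr` (each needs >= 3 samples).
#' @param aggregate `"max"` (default) or `"mean"` over gene pairs.
#' @return the [ReactionGraph-class] with edge attributes `weight_<group>`.
#' @export
weightEdges <- function(rg, expr, groups = NULL,
                        aggregate = c("max", "mean")) {
  stopifnot(is(rg, "ReactionGraph"), is(expr, "FeatureMatrix"))
  aggregate <- match.arg(aggregate)
  aggFun <- if (aggregate == "max") max else mean
  grp <- groupLabels(expr)
  if (is.null(groups)) groups <- unique(grp)
  v <- intensities(expr)
  g <- rg@graph
  genesOf <- igraph::V(g)$genes
  names(genesOf) <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  for (gr in groups) {
    cols <- which(grp == gr)
    if (length(cols) < 3)
      stop(sprintf("group '%s' has < 3 samples", gr))
    vg <- v[, cols, drop = FALSE]
    w <- rep(NA_real_, nrow(el))
    unmeasured <- rep(FALSE, nrow(el))
    for (i in seq_len(nrow(el))) {
      g1 <- intersect(genesOf[[el[i, 1]]], rownames(vg))
      g2 <- intersect(genesOf[[el[i, 2]]], rownames(vg))
      if (!length(g1) || !length(g2)) {
        unmeasured[i] <- TRUE
        next
      }
      cc <- suppressWarnings(
        cor(t(vg[g1, , drop = FALSE]), t(vg[g2, , drop = FALSE])))
      cc <- cc[is.finite(cc)]
      if (!length(cc)) {
        unmeasured[i] <- TRUE
        next
      }
      w[i] <- aggFun(cc)
    }
    med <- median(w, na.rm = TRUE)
    w[unmeasured] <- med
    g <- igraph::set_edge_attr(g, paste0("weight_", gr), value = w)
    g <- igraph::set_edge_attr(g, paste0("unmeasured_", gr),
                               value = unmeasured)
  }
  methods::new("ReactionGraph", graph = g,
               groups = union(rg@groups, groups))
}

# Enumerate simple paths from source-like to sink-like nodes; returns a
# list of character vectors of vertex names. Falls back to all vertices as
# sources/sinks when the graph has none (cyclic graphs).
.simplePaths <- function(g, maxPaths = 200000L) {
  sources <- igraph::V(g)[igraph::degree(g, mode = "in") == 0]
  sinks <- igraph::V(g)[igraph::degree(g, mode = "out") == 0]
  if (!length(sources)) sources <- igraph::V(g)
  if (!length(sinks)) sinks <- igraph::V(g)
  out <- list()
  for (s in sources) {
    ps <- igraph::all_simple_paths(g, from = s, to = sinks, mode = "out")
    out <- c(out, lapply(ps, function(p) igraph::V(g)$name[as.integer(p)]))
    if (length(out) > maxPaths)
      stop("path enumeration exceeded maxPaths; graph too dense")
  }
  unique(out)
}

#' Extract the top-scoring simple reaction paths for a group
#'
#' Simple paths between source-like (zero in-degree) and sink-like (zero
#' out-degree) reactions are enumerated, scored by the mean of the group's
#' edge weights, and the `k` best with at least `minLength` edges returned.
#' Ordering is deterministic: score descending, then lexicographic node
#' sequence.
#'
#' @param rg a weighted [ReactionGraph-class]
#' @param group group label whose weights to score with.
#' @param k number of paths, default 50.
#' @param minLength minimum edge count, default 6.
#' @return a [MetabolicPathSet-class] (empty, with a warning, if no path
#'   qualifies).
#' @export
extractTopPaths <- function(rg, group, k = 50, minLength = 6) {
  stopifnot(is(rg, "ReactionGraph"))
  wAttr <- paste0("weight_", group)
  if (!wAttr %in% igraph::edge_attr_names(rg@graph))
    stop("no weights for group '", group, "'; run weightEdges first")
  g <- rg@graph
  paths <- .simplePaths(g)
  paths <- paths[vapply(paths, length, integer(1)) >= minLength + 1]
  if (!length(paths)) {
    warning("no path with >= ", minLength, " edges")
    return(methods::new("MetabolicPathSet", paths = list(),
                        score = numeric(), length = integer(),
                        condition = character()))
  }
  wAll <- igraph::edge_attr(g, wAttr)
  score <- vapply(paths, function(p) {
    eid <- igraph::get_edge_ids(g, rbind(p[-length(p)], p[-1]))
    mean(wAll[eid])
  }, numeric(1))
  seqStr <- vapply(paths, paste, character(1), collapse = "\r")
  ord <- order(-score, seqStr)
  ord <- ord[seq_len(min(k, length(ord)))]
  methods::new("MetabolicPathSet",
               paths = paths[ord],
               score = score[ord],
               length = vapply(paths[ord], length, integer(1)) - 1L,
               condition = rep(as.character(group), length(ord)))
}

#' Combine path sets from several conditions
#' @param ... [MetabolicPathSet-class] objects.
#' @return a single [MetabolicPathSet-class]
#' @export
combinePathSets <- function(...) {
  sets <- list(...)
  methods::new("MetabolicPathSet",
               paths = do.call(c, lapply(sets, function(s) s@paths)),
               score = do.call(c, lapply(sets, function(s) s@score)),
               length = do.call(c, lapply(sets, function(s) s@length)),
               condition = do.call(c, lapply(sets, function(s) s@condition)))
}

# log P(sequence | component): initial + transitions, both smoothed.
.pathLogLik <- function(seqIdx, logInit, logTrans) {
  ll <- logInit[seqIdx[1]]
  if (length(seqIdx) > 1)
    ll <- ll + sum(logTrans[cbind(seqIdx[-length(seqIdx)], seqIdx[-1])])
  ll
}

#' Train a two-component Markov-mixture path classifier
#'
#' Fits a mixture of two first-order Markov chains over reaction-node
#' sequences by EM with Laplace (add-`alpha`) smoothing of initial and
#' transition probabilities. Training is semi-supervised: each path carries
#' a fixed prior of `labelWeight` on the component matching its own
#' condition, which ties component 1 to condition 1 and prevents component
#' starvation when the two conditions' paths look alike; at
#' classification time the mixture weights are the training class
#' proportions. With smoothing this is MAP-EM: the penalized
#' (posterior) objective is guaranteed non-decreasing and is used for
#' convergence; the observed-data log-likelihood trace is also recorded.
#' After fitting, each component is associated with the condition whose
#' training paths it best explains (majority posterior).
#'
#' @param pathSet a [MetabolicPathSet-class] with exactly two conditions
#'   and at least 5 paths per condition.
#' @param alpha Laplace pseudo-count, default 1.
#' @param maxIter EM iteration cap, default 200.
#' @param tol convergence tolerance on the penalized objective, default 1e-6.
#' @param seed integer seed (recorded for provenance; the fit itself is
#'   deterministic given the inputs).
#' @param labelWeight per-path prior on the component matching the path's
#'   own training condition, in (0.5, 1); default 0.85.
#' @return a [PathClassifierModel-class]
#' @export
trainPathClassifier <- function(pathSet, alpha = 1, maxIter = 200,
                                tol = 1e-6, seed = 1L, labelWeight = 0.85) {
  stopifnot(is(pathSet, "MetabolicPathSet"))
  conds <- unique(pathSet@condition)
  if (length(conds) != 2)
    stop("need paths from exactly two conditions, got: ",
         paste(conds, collapse = ", "))
  if (any(table(pathSet@condition) < 5))
    stop("need >= 5 paths per condition")
  alphabet <- sort(unique(unlist(pathSet@paths)))
  A <- length(alphabet)
  seqs <- lapply(pathSet@paths, function(p) match(p, alphabet))
  n <- length(seqs)

  # semi-supervised anchoring: each path carries a fixed per-path component
  # prior favouring its training condition (soft labels, weight
  # `labelWeight`). Component c is thereby tied to condition c; the E-step
  # combines these priors with the sequence likelihoods, so uninformative
  # data leave the posteriors at the priors instead of collapsing one
  # component.
  set.seed(as.integer(seed))
  priorMat <- cbind(ifelse(pathSet@condition == conds[1], labelWeight,
                           1 - labelWeight),
                    ifelse(pathSet@condition == conds[2], labelWeight,
                           1 - labelWeight))
  resp <- priorMat

  mstep <- function(resp) {
    lapply(1:2, function(c) {
      r <- resp[, c]
      init <- rep(alpha, A)
      trans <- matrix(alpha, A, A)
      for (i in seq_len(n)) {
        s <- seqs[[i]]
        init[s[1]] <- init[s[1]] + r[i]
        if (length(s) > 1) {
          idx <- cbind(s[-length(s)], s[-1])
          for (j in seq_len(nrow(idx)))
            trans[idx[j, 1], idx[j, 2]] <- trans[idx[j, 1], idx[j, 2]] + r[i]
        }
      }
      list(initial = setNames(init / sum(init), alphabet),
           transition = trans / rowSums(trans))
    })
  }

  logPrior <- function(comps) {
    # Dirichlet(alpha + 1) log-density kernel of all parameter rows
    sum(vapply(comps, function(cmp)
      alpha * (sum(log(cmp$initial)) + sum(log(cmp$transition))),
      numeric(1)))
  }

  # class-prior mixture weights from the training labels, held fixed: each
  # component represents one condition, so its prior is that condition's
  # share of the training paths (also prevents component starvation on
  # uninformative data)
  lambda <- c(mean(pathSet@condition == conds[1]),
              mean(pathSet@condition == conds[2]))
  comps <- mstep(resp)
  llTrace <- numeric()
  objTrace <- numeric()
  for (it in seq_len(maxIter)) {
    lmat <- vapply(1:2, function(c) {
      li <- log(comps[[c]]$initial)
      lt <- log(comps[[c]]$transition)
      vapply(seqs, .pathLogLik, numeric(1), logInit = li, logTrans = lt)
    }, numeric(n))
    lj <- lmat + log(priorMat)
    mx <- apply(lj, 1, max)
    ll <- sum(mx + log(rowSums(exp(lj - mx))))
    obj <- ll + logPrior(comps)
    llTrace <- c(llTrace, ll)
    objTrace <- c(objTrace, obj)
    resp <- exp(lj - mx)
    resp <- resp / rowSums(resp)
    comps <- mstep(resp)
    if (it > 1 && abs(objTrace[it] - objTrace[it - 1]) < tol) break
  }

  condLabels <- pathSet@condition
  meanPost1 <- vapply(conds, function(cd)
    mean(resp[condLabels == cd, 1]), numeric(1))
  first <- conds[which.max(meanPost1)]
  conditionOf <- c(first, setdiff(conds, first))

  methods::new("PathClassifierModel",
               components = comps, mixtureWeights = lambda,
               conditionOf = conditionOf,
               logLik = llTrace, objective = objTrace,
               alphabet = alphabet)
}

# Posterior probability of each component for each path.
.posteriors <- function(model, pathSet) {
  seqs <- lapply(pathSet@paths, function(p) {
    idx <- match(p, model@alphabet)
    if (anyNA(idx))
      stop("path contains reactions outside the model alphabet: ",
           paste(p[is.na(idx)], collapse = ", "))
    idx
  })
  n <- length(seqs)
  lmat <- vapply(1:2, function(c) {
    li <- log(model@components[[c]]$initial)
    lt <- log(model@components[[c]]$transition)
    vapply(seqs, .pathLogLik, numeric(1), logInit = li, logTrans = lt)
  }, numeric(n))
  lj <- sweep(lmat, 2, log(model@mixtureWeights), "+")
  mx <- apply(lj, 1, max)
  post <- exp(lj - mx)
  post / rowSums(post)
}

# ROC by threshold sweep; score high = positive. Returns points + AUC.
.roc <- function(score, positive) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(score[positive] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score[!positive] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Classify paths and report ROC curves
#'
#' Scores each path by the posterior probability of the component associated
#' with the first condition label and reports the ROC (threshold sweep,
#' trapezoid AUC) of that score against the true labels, plus per-component
#' ROC curves (M1/M2 convention: the component tied to the other condition
#' yields an AUC below 0.5).
#'
#' @param model a [PathClassifierModel-class]
#' @param pathSet a [MetabolicPathSet-class]
#' @param labels character vector of true condition labels (default: the
#'   path set's own `condition` field); must contain both conditions.
#' @return list with `auc`, `roc` (points of the combined classifier),
#'   `posterior` (per-path score), `positive_condition` and `components`
#'   (per-component `auc` and `roc`).
#' @export
classifyPaths <- function(model, pathSet, labels = NULL) {
  stopifnot(is(model, "PathClassifierModel"),
            is(pathSet, "MetabolicPathSet"))
  if (is.null(labels)) labels <- pathSet@condition
  if (length(unique(labels)) < 2)
    stop("labels contain a single class; ROC undefined")
  post <- .posteriors(model, pathSet)
  posCond <- model@conditionOf[1]
  positive <- labels == posCond
  main <- .roc(post[, 1], positive)
  compRoc <- lapply(1:2, function(c) {
    r <- .roc(post[, c], positive)
    list(component = paste0("M", c),
         associated_condition = model@conditionOf[c],
         auc = r$auc, roc = r$points)
  })
  list(auc = main$auc, roc = main$points, posterior = post[, 1],
       positive_condition = posCond, components = compRoc)
}

#' Label the union of two path sets' edges by condition exclusivity
#'
#' Builds the union graph of all edges used by either condition's paths and
#' labels each edge `exclusive_<A>`, `exclusive_<B>` or `shared`.
#'
#' @param pathsA,pathsB [MetabolicPathSet-class] objects from the same base
#'   graph (single condition each).
#' @return list with `graph` (igraph with edge attribute `status`) and
#'   `counts` (nodes, edges, exclusive_A, exclusive_B, shared).
#' @export
extractSubnetwork <- function(pathsA, pathsB) {
  edgesOf <- function(ps) {
    if (!length(ps@paths)) return(character())
    unique(unlist(lapply(ps@paths, function(p)
      paste(p[-length(p)], p[-1], sep = "\r"))))
  }
  eA <- edgesOf(pathsA)
  eB <- edgesOf(pathsB)
  condA <- if (length(pathsA@condition)) pathsA@condition[1] else "A"
  condB <- if (length(pathsB@condition)) pathsB@condition[1] else "B"
  all <- union(eA, eB)
  status <- ifelse(all %in% eA & all %in% eB, "shared",
                   ifelse(all %in% eA, paste0("exclusive_", condA),
                          paste0("exclusive_", condB)))
  parts <- strsplit(all, "\r", fixed = TRUE)
  ed <- data.frame(from = vapply(parts, `[`, character(1), 1),
                   to = vapply(parts, `[`, character(1), 2),
                   status = status, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = TRUE)
  list(graph = g,
       counts = list(nodes = igraph::vcount(g), edges = nrow(ed),
                     exclusive_A = sum(status == paste0("exclusive_", condA)),
                     exclusive_B = sum(status == paste0("exclusive_", condB)),
                     shared = sum(status == "shared")))
}

#' Project differential results onto a subnetwork
#'
#' Annotates each reaction node `up`, `down` or `undetected` from the mapped
#' differential feature with the largest |logFC| among significant features
#' (raw rule), and reports the coverage fraction (nodes with any mapped
#' measured feature).
#'
#' @param subnetwork output of [extractSubnetwork()].
#' @param diff differential results data.frame (`feature_id`, `logFC`,
#'   `significant_raw`).
#' @param geneMap data.frame `gene` -> `feature_id` linking reaction gene
#'   annotations to differential features.
#' @param reactionGenes named list: genes per reaction id (e.g. from the
#'   [ReactionGraph-class] vertex annotations).
#' @return list with `graph` (node attribute `regulation`), `coverage`
#'   (fraction of nodes with a mapped measured feature) and `regulation`
#'   (named character).
#' @export
projectDifferential <- function(subnetwork, diff, geneMap, reactionGenes) {
  g <- subnetwork$graph
  nodes <- igraph::V(g)$name
  lfc <- setNames(diff$logFC, diff$feature_id)
  sig <- setNames(diff$significant_raw, diff$feature_id)
  reg <- setNames(rep("undetected", length(nodes)), nodes)
  covered <- setNames(rep(FALSE, length(nodes)), nodes)
  for (nd in nodes) {
    genes <- reactionGenes[[nd]]
    if (is.null(genes)) next
    feats <- unique(geneMap$feature_id[geneMap$gene %in% genes])
    feats <- feats[feats %in% names(lfc)]
    if (!length(feats)) next
    covered[nd] <- TRUE
    sigFeats <- feats[sig[feats] %in% TRUE]
    if (!length(sigFeats)) next
    best <- sigFeats[which.max(abs(lfc[sigFeats]))]
    reg[nd] <- if (lfc[best] > 0) "up" else "down"
  }
  g <- igraph::set_vertex_attr(g, "regulation", value = unname(reg[nodes]))
  list(graph = g, coverage = mean(covered), regulation = reg)
}

#' Export a graph as SIF
#'
#' One line per edge: `source<TAB>interaction<TAB>target`; the interaction
#' term is the edge `status` attribute when present, else `"rr"`.
#'
#' @param g an igraph object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  inter <- if ("status" %in% igraph::edge_attr_names(g))
    igraph::E(g)$status else rep("rr", nrow(el))
  writeLines(paste(el[, 1], inter, el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Export a graph as GraphML
#' @param g an igraph object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGraphml <- function(g, path) {
  # igraph cannot serialize list-typed vertex attributes; flatten them
  for (at in igraph::vertex_attr_names(g)) {
    if (is.list(igraph::vertex_attr(g, at)))
      g <- igraph::set_vertex_attr(g, at, value = vapply(
        igraph::vertex_attr(g, at), paste, character(1), collapse = ";"))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a path set as TSV
#'
#' Columns `rank, condition, score, length, node_sequence`.
#'
#' @param pathSet a [MetabolicPathSet-class]
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePathsTsv <- function(pathSet, path) {
  utils::write.table(as.data.frame(pathSet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROC points as CSV
#' @param classification output of [classifyPaths()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRocCsv <- function(classification, path) {
  write.csv(classification$roc, path, row.names = FALSE)
  invisible(path)
}
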