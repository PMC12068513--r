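# Internal molecular-graph representation and a SMILES reader/writer for the
# dialect Open Babel's canonical writer emits. The graph is what the fragment
# surgery (bond cleavage, marked attachment, capping) operates on; Open Babel
# remains the authority for canonical forms and aromaticity perception, so
# graphs are (re)built from canonical SMILES at operation boundaries.
#
# Graph layout (plain list, parallel atom vectors + bond table):
#   elem   character  element symbol; "*" is an attachment wildcard
#   arom   logical    aromatic atom flag (lowercase in SMILES)
#   charge integer    formal charge
#   hcount integer    explicit hydrogen count from a bracket atom; NA = implicit
#   iso    integer    isotope label; on "*" atoms it encodes the mark (iso =
#                     mark + 1, because isotope 0 is not writable in SMILES)
#   bond   integer matrix m x 2 (atom indices)
#   border integer    bond order 1/2/3 (aromatic bonds stored as 1)
#   barom  logical    aromatic bond flag

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s", "se", "as")

DEFAULT_VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, P = 3L, S = 2L,
                     Cl = 1L, Br = 1L, I = 1L, Se = 2L, Si = 4L)

empty_graph <- function() {
  list(elem = character(0), arom = logical(0), charge = integer(0),
       hcount = integer(0), iso = integer(0),
       bond = matrix(integer(0), ncol = 2), border = integer(0),
       barom = logical(0))
}

graph_n_atoms <- function(g) length(g$elem)
graph_n_bonds <- function(g) nrow(g$bond)

# heavy atoms exclude wildcards
graph_heavy_atoms <- function(g) sum(g$elem != "*")

graph_add_atom <- function(g, elem, arom = FALSE, charge = 0L, hcount = NA_integer_,
                           iso = NA_integer_) {
  g$elem <- c(g$elem, elem)
  g$arom <- c(g$arom, arom)
  g$charge <- c(g$charge, as.integer(charge))
  g$hcount <- c(g$hcount, as.integer(hcount))
  g$iso <- c(g$iso, as.integer(iso))
  g
}

graph_add_bond <- function(g, a, b, order = 1L, arom = FALSE) {
  g$bond <- rbind(g$bond, c(as.integer(a), as.integer(b)))
  g$border <- c(g$border, as.integer(order))
  g$barom <- c(g$barom, arom)
  g
}

# ---------------------------------------------------------------------------
# SMILES reader

parse_smiles_graph <- function(smi) {
  g <- empty_graph()
  implicit_bond <- logical(0)   # bonds written with no symbol
  chars <- strsplit(smi, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  prev <- 0L
  pend <- NA_character_
  stack <- integer(0)
  ring <- list()                # digit label -> list(atom, sym)

  add_parsed_bond <- function(a, b, sym) {
    implied <- is.na(sym)
    if (implied) sym <- "-"
    order <- switch(sym, "-" = 1L, "/" = 1L, "\\" = 1L, ":" = 1L,
                    "=" = 2L, "#" = 3L,
                    stop("unsupported bond symbol '", sym, "'", call. = FALSE))
    g <<- graph_add_bond(g, a, b, order, arom = identical(sym, ":"))
    implicit_bond <<- c(implicit_bond, implied)
  }

  new_atom <- function(elem, arom, charge = 0L, hcount = NA_integer_,
                       iso = NA_integer_) {
    g <<- graph_add_atom(g, elem, arom, charge, hcount, iso)
    cur <- graph_n_atoms(g)
    if (prev > 0L) add_parsed_bond(prev, cur, pend)
    pend <<- NA_character_
    prev <<- cur
  }

  close_ring <- function(lab) {
    if (!is.null(ring[[lab]])) {
      op <- ring[[lab]]
      sym <- if (!is.na(op$sym)) op$sym else pend
      add_parsed_bond(op$atom, prev, sym)
      ring[[lab]] <<- NULL
    } else {
      ring[[lab]] <<- list(atom = prev, sym = pend)
    }
    pend <<- NA_character_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES '", smi, "'", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend <- ch; i <- i + 1L
    } else if (ch == ".") {
      stop("disconnected (multi-component) SMILES are not supported: '",
           smi, "'", call. = FALSE)
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("bad ring closure in '", smi, "'", call. = FALSE)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in '", smi, "'", call. = FALSE)
      at <- parse_bracket_atom(paste(chars[(i + 1L):(j - 1L)], collapse = ""), smi)
      new_atom(at$elem, at$arom, at$charge, at$hcount, at$iso)
      i <- j + 1L
    } else if (ch == "*") {
      new_atom("*", FALSE); i <- i + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        new_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        new_atom(ch, FALSE); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        new_atom(toupper(ch), TRUE); i <- i + 1L
      } else {
        stop("cannot parse SMILES '", smi, "' at character '", ch, "'",
             call. = FALSE)
      }
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES '", smi, "'", call. = FALSE)
  if (length(ring)) stop("unclosed ring bond in SMILES '", smi, "'", call. = FALSE)
  if (graph_n_atoms(g) == 0L) stop("empty SMILES", call. = FALSE)

  # resolve implicit bonds between two aromatic atoms: aromatic if the bond is
  # in a ring, plain single otherwise (e.g. the inter-ring bond of biphenyl)
  if (graph_n_bonds(g)) {
    cand <- which(implicit_bond & g$arom[g$bond[, 1]] & g$arom[g$bond[, 2]] &
                    !g$barom)
    if (length(cand)) {
      rb <- graph_ring_bonds(g)
      g$barom[cand[rb[cand]]] <- TRUE
    }
  }
  g
}

# bracket atom body, e.g. "7*", "nH", "se", "O-", "13CH3", "N+"
parse_bracket_atom <- function(body, smi) {
  iso <- NA_integer_
  m <- regmatches(body, regexpr("^[0-9]+", body))
  if (length(m) && nzchar(m)) {
    iso <- as.integer(m)
    body <- sub("^[0-9]+", "", body)
  }
  arom <- FALSE
  if (grepl("^(se|as)", body)) {
    elem <- paste0(toupper(substr(body, 1, 1)), substr(body, 2, 2))
    arom <- TRUE
    body <- substr(body, 3, nchar(body))
  } else if (grepl("^[A-Z][a-z]", body) &&
             !grepl("^[A-Z]H", body)) {
    elem <- substr(body, 1, 2)
    body <- substr(body, 3, nchar(body))
  } else if (grepl("^[A-Z]", body)) {
    elem <- substr(body, 1, 1)
    body <- substr(body, 2, nchar(body))
  } else if (grepl("^[bcnops]", body)) {
    elem <- toupper(substr(body, 1, 1))
    arom <- TRUE
    body <- substr(body, 2, nchar(body))
  } else if (grepl("^\\*", body)) {
    elem <- "*"
    body <- substr(body, 2, nchar(body))
  } else {
    stop("cannot parse bracket atom '[", body, "]' in '", smi, "'", call. = FALSE)
  }
  body <- gsub("@+[A-Z]*[0-9]*", "", body)     # stereo passed through, dropped
  hcount <- 0L
  m <- regmatches(body, regexpr("H[0-9]*", body))
  if (length(m) && nzchar(m)) {
    hcount <- if (nchar(m) > 1L) as.integer(substr(m, 2, nchar(m))) else 1L
    body <- sub("H[0-9]*", "", body)
  }
  charge <- 0L
  m <- regmatches(body, regexpr("(\\+[0-9]+|-[0-9]+|\\++|-+)", body))
  if (length(m) && nzchar(m)) {
    charge <- if (grepl("^[+-][0-9]", m)) {
      as.integer(m)
    } else {
      (nchar(m)) * (if (substr(m, 1, 1) == "+") 1L else -1L)
    }
    body <- sub("(\\+[0-9]+|-[0-9]+|\\++|-+)", "", body)
  }
  body <- sub(":[0-9]+$", "", body)            # atom class dropped
  if (elem == "*") {
    # wildcards carry no hydrogens
    hcount <- NA_integer_
  }
  list(elem = elem, arom = arom, charge = charge,
       hcount = if (elem == "*") NA_integer_ else hcount, iso = iso)
}

# ---------------------------------------------------------------------------
# ring perception: a bond is a ring bond iff it is not a bridge (Tarjan)

graph_ring_bonds <- function(g) {
  n <- graph_n_atoms(g)
  m <- graph_n_bonds(g)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n)
  for (b in seq_len(m)) {
    adj[[g$bond[b, 1]]] <- c(adj[[g$bond[b, 1]]], b)
    adj[[g$bond[b, 2]]] <- c(adj[[g$bond[b, 2]]], b)
  }
  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  # iterative DFS with explicit stack (frames: atom, incoming bond, edge ptr)
  for (start in seq_len(n)) {
    if (disc[start] != 0L) next
    stack <- list(list(v = start, pe = 0L, i = 1L))
    timer <- timer + 1L; disc[start] <- low[start] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i <= length(adj[[v]])) {
        b <- adj[[v]][fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (b == fr$pe) next
        u <- if (g$bond[b, 1] == v) g$bond[b, 2] else g$bond[b, 1]
        if (disc[u] == 0L) {
          timer <- timer + 1L; disc[u] <- low[u] <- timer
          stack[[length(stack) + 1L]] <- list(v = u, pe = b, i = 1L)
        } else {
          low[v] <- min(low[v], disc[u])
          stack[[length(stack)]]$vlow <- low[v]
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

graph_neighbors <- function(g, i) {
  hit <- g$bond[, 1] == i | g$bond[, 2] == i
  setdiff(as.vector(g$bond[hit, , drop = FALSE]), i)
}

graph_bonds_at <- function(g, i) which(g$bond[, 1] == i | g$bond[, 2] == i)

# connected component membership (integer labels, 1-based)
graph_components <- function(g) {
  n <- graph_n_atoms(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in graph_neighbors(g, v)) {
        if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
      }
    }
  }
  comp
}

# keep the given atoms (reindexing bonds); drops bonds that cross the cut
graph_subset <- function(g, keep) {
  keep <- sort(unique(as.integer(keep)))
  idx <- integer(graph_n_atoms(g)); idx[keep] <- seq_along(keep)
  bkeep <- g$bond[, 1] %in% keep & g$bond[, 2] %in% keep
  list(elem = g$elem[keep], arom = g$arom[keep], charge = g$charge[keep],
       hcount = g$hcount[keep], iso = g$iso[keep],
       bond = matrix(idx[g$bond[bkeep, , drop = FALSE]], ncol = 2),
       border = g$border[bkeep], barom = g$barom[bkeep])
}

graph_delete_bond <- function(g, b) {
  g$bond <- g$bond[-b, , drop = FALSE]
  g$border <- g$border[-b]
  g$barom <- g$barom[-b]
  g
}

# concatenate two graphs; returns combined graph plus the index offset of g2
graph_union <- function(g1, g2) {
  off <- graph_n_atoms(g1)
  g <- list(elem = c(g1$elem, g2$elem), arom = c(g1$arom, g2$arom),
            charge = c(g1$charge, g2$charge), hcount = c(g1$hcount, g2$hcount),
            iso = c(g1$iso, g2$iso),
            bond = rbind(g1$bond, g2$bond + off),
            border = c(g1$border, g2$border), barom = c(g1$barom, g2$barom))
  list(graph = g, offset = off)
}

# implicit hydrogen count under the usual SMILES valence model
graph_implicit_h <- function(g, i) {
  if (!is.na(g$hcount[i])) return(g$hcount[i])
  if (g$elem[i] == "*") return(0L)
  dv <- DEFAULT_VALENCE[g$elem[i]]
  if (is.na(dv)) return(0L)
  bs <- graph_bonds_at(g, i)
  s <- sum(g$border[bs]) + as.integer(g$arom[i])
  max(0L, as.integer(dv) - s)
}

# ---------------------------------------------------------------------------
# SMILES writer (deterministic DFS; output is fed to Open Babel for
# canonicalisation, so every single bond is written explicitly)

atom_token <- function(g, i) {
  e <- g$elem[i]
  if (e == "*") {
    if (!is.na(g$iso[i])) return(paste0("[", g$iso[i], "*]")) else return("*")
  }
  sym <- if (g$arom[i]) tolower(e) else e
  plain <- e %in% ORGANIC_SUBSET && g$charge[i] == 0L && is.na(g$hcount[i]) &&
    is.na(g$iso[i]) && !(g$arom[i] && !tolower(e) %in% c("b", "c", "n", "o", "p", "s"))
  if (plain) return(sym)
  h <- if (is.na(g$hcount[i])) 0L else g$hcount[i]
  paste0("[",
         if (!is.na(g$iso[i])) g$iso[i] else "",
         sym,
         if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
         if (g$charge[i] > 0L) paste0("+", if (g$charge[i] > 1L) g$charge[i] else ""),
         if (g$charge[i] < 0L) paste0("-", if (g$charge[i] < -1L) -g$charge[i] else ""),
         "]")
}

bond_token <- function(g, b) {
  if (g$barom[b]) return("")
  switch(g$border[b], "-", "=", "#")
}

ring_label <- function(k) if (k < 10L) as.character(k) else sprintf("%%%02d", k)

write_smiles_graph <- function(g) {
  n <- graph_n_atoms(g)
  if (n == 0L) return("")
  m <- graph_n_bonds(g)
  adj <- vector("list", n)
  if (m) {
    for (b in seq_len(m)) {
      adj[[g$bond[b, 1]]] <- c(adj[[g$bond[b, 1]]], b)
      adj[[g$bond[b, 2]]] <- c(adj[[g$bond[b, 2]]], b)
    }
  }
  visited <- logical(n)
  bond_used <- logical(m)       # tree edges
  ring_at <- vector("list", n)  # atom -> list of (label, bond, first)
  ring_ct <- 0L

  # first pass: classify tree vs ring-closure edges (iterative DFS)
  visited[1] <- TRUE
  dfs <- list(1L)
  while (length(dfs)) {
    v <- dfs[[length(dfs)]]; dfs[[length(dfs)]] <- NULL
    for (b in adj[[v]]) {
      if (bond_used[b]) next
      u <- if (g$bond[b, 1] == v) g$bond[b, 2] else g$bond[b, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        bond_used[b] <- TRUE
        dfs[[length(dfs) + 1L]] <- u
      }
    }
  }
  if (!all(visited)) stop("cannot write disconnected graph", call. = FALSE)
  ring_edges <- which(!bond_used)
  for (b in ring_edges) {
    ring_ct <- ring_ct + 1L
    lab <- ring_label(ring_ct)
    a1 <- g$bond[b, 1]; a2 <- g$bond[b, 2]
    ring_at[[a1]] <- c(ring_at[[a1]], list(list(lab = lab, bond = b, first = TRUE)))
    ring_at[[a2]] <- c(ring_at[[a2]], list(list(lab = lab, bond = b, first = FALSE)))
  }

  # second pass: emit. recursive over the spanning tree
  visited2 <- logical(n)
  emit <- function(v) {
    visited2[v] <<- TRUE
    out <- atom_token(g, v)
    for (r in ring_at[[v]]) {
      out <- paste0(out, if (r$first) bond_token(g, r$bond) else "", r$lab)
    }
    kids <- list()
    for (b in adj[[v]]) {
      if (!bond_used[b]) next
      u <- if (g$bond[b, 1] == v) g$bond[b, 2] else g$bond[b, 1]
      if (visited2[u]) next
      kids[[length(kids) + 1L]] <- list(u = u, b = b)
    }
    if (length(kids)) {
      for (k in seq_along(kids)) {
        piece <- paste0(bond_token(g, kids[[k]]$b), emit(kids[[k]]$u))
        out <- if (k < length(kids)) paste0(out, "(", piece, ")")
               else paste0(out, piece)
      }
    }
    out
  }
  emit(1L)
}
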