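# Persistent (immutable) red-black tree over the intervals of a single
# sequence, augmented with the maximum interval end per subtree (max_end)
# so overlap search can prune.  Insertion is the functional four-case
# rebalancing scheme: an insert returns a new root sharing all untouched
# subtrees with the old one; existing trees are never modified, so any
# reference to a previous version remains valid.  Deletion is deliberately
# absent — sets are rebuilt, matching the package-wide immutability rule.
#
# Node: list(color, iv, max_end, left, right); empty subtree: NULL.
# Ordering key: (start, end); duplicates are routed right, so in-order
# traversal is sorted by (start, end) and stable for equal keys.

rb_node <- function(color, iv, left, right) {
  me <- iv$end
  if (!is.null(left) && left$max_end > me) me <- left$max_end
  if (!is.null(right) && right$max_end > me) me <- right$max_end
  list(color = color, iv = iv, max_end = me, left = left, right = right)
}

rb_key_less <- function(a, b) {
  a$start < b$start || (a$start == b$start && a$end < b$end)
}

# Four-case rebalance around a black node whose child+grandchild are red.
rb_balance <- function(color, iv, l, r) {
  if (color == "B") {
    if (!is.null(l) && l$color == "R") {
      if (!is.null(l$left) && l$left$color == "R") {
        return(rb_node("R", l$iv,
                       rb_node("B", l$left$iv, l$left$left, l$left$right),
                       rb_node("B", iv, l$right, r)))
      }
      if (!is.null(l$right) && l$right$color == "R") {
        return(rb_node("R", l$right$iv,
                       rb_node("B", l$iv, l$left, l$right$left),
                       rb_node("B", iv, l$right$right, r)))
      }
    }
    if (!is.null(r) && r$color == "R") {
      if (!is.null(r$left) && r$left$color == "R") {
        return(rb_node("R", r$left$iv,
                       rb_node("B", iv, l, r$left$left),
                       rb_node("B", r$iv, r$left$right, r$right)))
      }
      if (!is.null(r$right) && r$right$color == "R") {
        return(rb_node("R", r$iv,
                       rb_node("B", iv, l, r$left),
                       rb_node("B", r$right$iv, r$right$left, r$right$right)))
      }
    }
  }
  rb_node(color, iv, l, r)
}

rb_ins <- function(t, iv) {
  if (is.null(t)) {
    return(rb_node("R", iv, NULL, NULL))
  }
  if (rb_key_less(iv, t$iv)) {
    rb_balance(t$color, t$iv, rb_ins(t$left, iv), t$right)
  } else {
    rb_balance(t$color, t$iv, t$left, rb_ins(t$right, iv))
  }
}

rb_insert <- function(root, iv) {
  t <- rb_ins(root, iv)
  if (t$color == "R") rb_node("B", t$iv, t$left, t$right) else t
}

# In-order traversal into a preallocated list: sorted by (start, end).
rb_inorder <- function(root, n) {
  out <- vector("list", n)
  i <- 0L
  walk <- function(t) {
    if (is.null(t)) return(invisible(NULL))
    walk(t$left)
    i <<- i + 1L
    out[[i]] <<- t$iv
    walk(t$right)
  }
  walk(root)
  out[seq_len(i)]
}

# Overlap search with max_end pruning: a subtree whose max_end <= qstart
# cannot contain an overlap; a node whose start >= qend rules out its right
# subtree.  Results come out in (start, end) order.
rb_search_overlap <- function(root, qstart, qend) {
  out <- list()
  i <- 0L
  walk <- function(t) {
    if (is.null(t) || t$max_end <= qstart) return(invisible(NULL))
    walk(t$left)
    if (t$iv$start < qend) {
      if (qstart < t$iv$end) {
        i <<- i + 1L
        out[[i]] <<- t$iv
      }
      walk(t$right)
    }
  }
  walk(root)
  out
}

# Structural audit used by the test and acceptance suites.  Returns counts
# of violations of each red-black/augmentation invariant plus size/height.
rb_audit <- function(root) {
  red_red <- 0L
  max_end_bad <- 0L
  order_bad <- 0L
  black_heights <- integer(0)
  size <- 0L
  walk <- function(t, nblack) {
    if (is.null(t)) {
      black_heights[length(black_heights) + 1L] <<- nblack
      return(0L)
    }
    size <<- size + 1L
    if (t$color == "R") {
      if ((!is.null(t$left) && t$left$color == "R") ||
          (!is.null(t$right) && t$right$color == "R")) {
        red_red <<- red_red + 1L
      }
    }
    nb <- nblack + (t$color == "B")
    hl <- walk(t$left, nb)
    hr <- walk(t$right, nb)
    me <- t$iv$end
    if (!is.null(t$left)) {
      me <- max(me, t$left$max_end)
      if (!rb_key_less(t$left$iv, t$iv) && !identical(t$left$iv, t$iv)) {
        # left key must be strictly less (duplicates go right)
        if (!rb_key_less(t$left$iv, t$iv)) order_bad <<- order_bad + 1L
      }
    }
    if (!is.null(t$right)) {
      me <- max(me, t$right$max_end)
      if (rb_key_less(t$right$iv, t$iv)) order_bad <<- order_bad + 1L
    }
    if (me != t$max_end) max_end_bad <<- max_end_bad + 1L
    max(hl, hr) + 1L
  }
  height <- walk(root, 0L)
  list(size = size,
       height = height,
       red_red_violations = red_red,
       black_height_uniform = length(unique(black_heights)) == 1L,
       black_height_values = unique(black_heights),
       max_end_violations = max_end_bad,
       order_violations = order_bad,
       root_black = is.null(root) || root$color == "B",
       height_bound_ok = height <= 2 * log2(size + 1) + 1e-9)
}
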