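#!/usr/bin/env python
"""Reference Markov clustering, written directly from the canonical
expansion/inflation iteration on a column-stochastic matrix.

Usage: python mcl_reference.py input.json output.json

input.json: {"nodes": [...], "edges": [[a, b, w], ...],
             "inflation": float, "prune": float,
             "max_iter": int, "tol": float}
output.json: {"clusters": [[member, ...], ...]}

Conventions (shared with any faithful MCL implementation on these graphs):
self-loop weight equals the node's maximum incident edge weight; entries
below the pruning threshold are zeroed each iteration; after convergence,
attractors are the rows with positive diagonal and every node joins the
attractor it sends the most flow to (ties to the smallest node name);
isolated nodes are singletons.
"""
import json
import sys

import numpy as np


def mcl(nodes, edges, inflation, prune, max_iter, tol):
    n = len(nodes)
    idx = {v: i for i, v in enumerate(nodes)}
    W = np.zeros((n, n))
    for a, b, w in edges:
        i, j = idx[a], idx[b]
        W[i, j] = max(W[i, j], w)
        W[j, i] = W[i, j]
    np.fill_diagonal(W, W.max(axis=1))
    colsum = W.sum(axis=0)
    isolated = colsum == 0
    M = np.zeros((n, n))
    M[:, ~isolated] = W[:, ~isolated] / colsum[~isolated]
    for _ in range(max_iter):
        M2 = M @ M
        M2 = M2 ** inflation
        M2[M2 < prune] = 0.0
        cs = M2.sum(axis=0)
        nz = cs > 0
        M2[:, nz] = M2[:, nz] / cs[nz]
        delta = np.abs(M2 - M).max()
        M = M2
        if delta < tol:
            break
    clusters = {}
    attractors = [i for i in range(n) if M[i, i] > tol]
    for j in range(n):
        if isolated[j]:
            clusters.setdefault(("solo", j), []).append(nodes[j])
            continue
        flow = [(M[i, j], i) for i in attractors if M[i, j] > 0]
        if not flow:
            clusters.setdefault(("solo", j), []).append(nodes[j])
            continue
        best = max(f for f, _ in flow)
        cand = [i for f, i in flow if f == best]
        win = min(cand, key=lambda i: nodes[i])
        clusters.setdefault(("att", win), []).append(nodes[j])
    return sorted(sorted(c) for c in clusters.values())


def main():
    with open(sys.argv[1]) as fh:
        spec = json.load(fh)
    clusters = mcl(spec["nodes"], spec.get("edges", []),
                   spec.get("inflation", 2.0), spec.get("prune", 1e-5),
                   int(spec.get("max_iter", 200)), spec.get("tol", 1e-6))
    with open(sys.argv[2], "w") as fh:
        json.dump({"clusters": clusters}, fh)


if __name__ == "__main__":
    main()
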