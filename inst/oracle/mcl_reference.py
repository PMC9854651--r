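"""Reference Markov Cluster (MCL) implementation used as an independent
test oracle. Reads a JSON problem description, runs dense MCL with numpy,
and prints the resulting partition as JSON (list of sorted node-name lists,
sorted by decreasing size).

Input JSON: {"nodes": [...], "edges": [[a, b, score], ...],
             "inflation": float, "prune": float, "tol": float,
             "max_iter": int, "expansion": int, "self_loop": "max"|"one"}
"""
import json
import sys

import numpy as np


def column_normalize(m):
    cs = m.sum(axis=0)
    dead = cs == 0
    if dead.any():
        idx = np.where(dead)[0]
        m[idx, idx] = 1.0
        cs = m.sum(axis=0)
    return m / cs


def run(problem):
    nodes = list(problem["nodes"])
    index = {n: i for i, n in enumerate(nodes)}
    n = len(nodes)
    a = np.zeros((n, n))
    for u, v, s in problem["edges"]:
        a[index[u], index[v]] = s
        a[index[v], index[u]] = s
    if problem.get("self_loop", "max") == "max":
        loops = a.max(axis=0)
        loops[loops == 0] = 1.0
    else:
        loops = np.ones(n)
    np.fill_diagonal(a, loops)
    m = column_normalize(a)

    inflation = problem["inflation"]
    prune = problem.get("prune", 1e-5)
    tol = problem.get("tol", 1e-6)
    max_iter = problem.get("max_iter", 200)
    expansion = problem.get("expansion", 2)

    for _ in range(max_iter):
        prev = m
        m = np.linalg.matrix_power(prev, expansion)
        m = column_normalize(np.power(m, inflation))
        m[m < prune] = 0.0
        m = column_normalize(m)
        if np.abs(m - prev).max() < tol:
            break

    eps = 1e-7
    attractors = [i for i in range(n) if m[i, i] > eps]
    if not attractors:
        attractors = list(range(n))
    clusters = []  # list of sets of node indices
    for i in attractors:
        support = set(np.where(m[i, :] > eps)[0]) | {i}
        merged = [c for c in clusters if c & support]
        for c in merged:
            clusters.remove(c)
            support |= c
        clusters.append(support)
    assigned = set().union(*clusters) if clusters else set()
    for j in range(n):
        if j not in assigned:
            mass = [(m[i, j], i) for i in attractors]
            best = max(mass) if mass else (0.0, None)
            if best[0] > eps:
                for c in clusters:
                    if best[1] in c:
                        c.add(j)
                        break
            else:
                clusters.append({j})
            assigned.add(j)

    out = [sorted(nodes[i] for i in c) for c in clusters]
    out.sort(key=lambda c: (-len(c), c[0]))
    return out


if __name__ == "__main__":
    with open(sys.argv[1]) as fh:
        problem = json.load(fh)
    json.dump(run(problem), sys.stdout)
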