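"""Explicit Voronoi construction by brute force, used as a test oracle.

Enumerates all 4-subsets of atoms, keeps those whose circumsphere is empty
(these circumcenters are exactly the Voronoi vertices), and reports every
atom pair belonging to such a subset: the pairs whose Voronoi cells share a
ridge. Reads whitespace-separated xyz rows from each path on the command
line; for each file prints a "## <path>" header followed by one "i j" pair
per line (1-based, i<j).
"""
import sys
import itertools
import numpy as np


def ridge_pairs(pts):
    n = len(pts)
    quads = np.array(list(itertools.combinations(range(n), 4)))
    a = pts[quads[:, 0]]
    rel = pts[quads[:, 1:]] - a[:, None, :]          # (m,3,3)
    rhs = 0.5 * (rel ** 2).sum(axis=2)               # (m,3)
    det = np.linalg.det(rel)
    good = np.abs(det) > 1e-12
    centers = np.full((len(quads), 3), np.nan)
    centers[good] = np.linalg.solve(rel[good], rhs[good][..., None])[..., 0]
    r2 = (centers ** 2).sum(axis=1)
    cc = centers + a                                  # absolute circumcenters
    d2 = ((pts[None, :, :] - cc[:, None, :]) ** 2).sum(axis=2)  # (m,n)
    d2[np.arange(len(quads))[:, None], quads] = np.inf
    empty = good & (np.nanmin(d2, axis=1) > r2 * (1 + 1e-9))
    pairs = set()
    for q in quads[empty]:
        for i, j in itertools.combinations(sorted(map(int, q)), 2):
            pairs.add((i, j))
    return sorted(pairs)


for path in sys.argv[1:]:
    print("##", path)
    for i, j in ridge_pairs(np.loadtxt(path, ndmin=2)):
        print(i + 1, j + 1)
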