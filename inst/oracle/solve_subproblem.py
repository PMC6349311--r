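"""Independent oracle for the CAA convex half-step.

Solves  max_u  g'u  s.t.  ||u||_2 <= 1,  ||u||_1 <= c,  u_i = 0 for i in F
with a general-purpose constrained solver (SLSQP), via the standard
positive/negative split u = p - n (p, n >= 0) that makes the L1 constraint
smooth. Reads a JSON list of instances {g, c, forbidden} on stdin (indices
1-based), writes a JSON list of optimal objective values on stdout.
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize


def solve(g, c, forbidden):
    g = np.asarray(g, dtype=float)
    free = np.array([i for i in range(g.size) if (i + 1) not in set(forbidden)])
    if free.size == 0:
        return 0.0
    gf = g[free]
    d = gf.size
    # variables x = [p, n], u = p - n
    def neg_obj(x):
        return -gf @ (x[:d] - x[d:])

    def neg_obj_grad(x):
        return np.concatenate([-gf, gf])

    cons = [
        {"type": "ineq",
         "fun": lambda x: 1.0 - np.sum((x[:d] - x[d:]) ** 2),
         "jac": lambda x: np.concatenate([-2 * (x[:d] - x[d:]),
                                          2 * (x[:d] - x[d:])])},
        {"type": "ineq",
         "fun": lambda x: c - np.sum(x),
         "jac": lambda x: -np.ones(2 * d)},
    ]
    bounds = [(0, None)] * (2 * d)
    best = 0.0
    # linear objective over a convex set: any KKT point is global, but run a
    # few starts to be safe against solver stalls
    starts = []
    u0 = gf / max(np.linalg.norm(gf), 1e-12)
    for scale in (1.0, 0.5):
        u = u0 * scale
        l1 = np.abs(u).sum()
        if l1 > c:
            u = u * (c / l1)
        starts.append(np.concatenate([np.maximum(u, 0), np.maximum(-u, 0)]))
    starts.append(np.zeros(2 * d))
    for x0 in starts:
        res = minimize(neg_obj, x0, jac=neg_obj_grad, bounds=bounds,
                       constraints=cons, method="SLSQP",
                       options={"maxiter": 500, "ftol": 1e-12})
        if res.success or res.status in (0, 8):
            best = max(best, -res.fun)
    return best


def main():
    instances = json.load(sys.stdin)
    out = [solve(inst["g"], inst["c"], inst.get("forbidden", [])) for inst in instances]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
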