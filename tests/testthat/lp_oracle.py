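"""Independent LP oracle for the flow solver tests.

Reads a JSON problem {"from": [...], "to": [...], "cost": [...],
"cap": [...], "gamma": g} on stdin, solves
    min sum(cost * f) - gamma * (flow out of S)
s.t. conservation at every node except S and K, 0 <= f <= cap,
with scipy's HiGHS, and prints {"objective": ..., "status": ...}.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def main():
    prob = json.load(sys.stdin)
    src, dst = prob["from"], prob["to"]
    cost = np.asarray(prob["cost"], dtype=float)
    cap = np.asarray(prob["cap"], dtype=float)
    gamma = float(prob["gamma"])
    m = len(src)
    nodes = sorted(set(src) | set(dst))
    inner = [n for n in nodes if n not in ("__S__", "__K__")]
    idx = {n: i for i, n in enumerate(inner)}
    a_eq = np.zeros((len(inner), m))
    for e in range(m):
        if dst[e] in idx:
            a_eq[idx[dst[e]], e] += 1.0
        if src[e] in idx:
            a_eq[idx[src[e]], e] -= 1.0
    c = cost.copy()
    for e in range(m):
        if src[e] == "__S__":
            c[e] -= gamma
    res = linprog(c, A_eq=a_eq, b_eq=np.zeros(len(inner)),
                  bounds=list(zip(np.zeros(m), cap)), method="highs")
    json.dump({"objective": float(res.fun), "status": res.status}, sys.stdout)


if __name__ == "__main__":
    main()
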