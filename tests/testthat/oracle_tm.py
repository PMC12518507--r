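"""Independent TM-score oracle: maximizes the TM sum over rigid transforms
by direct numerical optimization (rotation-vector parameterization, many
seeded restarts), rather than the fragment-seeded iterative scheme. Inputs:
two TSV atom tables; CA atoms of chain R are compared. Prints the score."""
import sys
import numpy as np
from scipy.optimize import minimize
from scipy.spatial.transform import Rotation


def load_ca(path):
    rows = []
    with open(path) as fh:
        next(fh)
        for line in fh:
            ch, ri, at, x, y, z = line.split("\t")
            if ch == "R" and at == "CA":
                rows.append((int(ri), float(x), float(y), float(z)))
    rows.sort()
    return np.array([r[1:] for r in rows])


def main(nat_path, prd_path):
    a = load_ca(nat_path)
    b = load_ca(prd_path)
    L = len(a)
    d0 = max(0.5, 1.24 * np.cbrt(L - 15) - 1.8) if L > 15 else 0.5

    def neg_tm(params):
        rot = Rotation.from_rotvec(params[:3]).as_matrix()
        t = params[3:]
        d = np.linalg.norm(b @ rot.T + t - a, axis=1)
        return -np.mean(1 / (1 + (d / d0) ** 2))

    rng = np.random.default_rng(0)
    # Kabsch start
    cr, cm = a.mean(0), b.mean(0)
    h = (b - cm).T @ (a - cr)
    u, s, vt = np.linalg.svd(h)
    dsign = np.sign(np.linalg.det(u @ vt))
    r0 = (u @ np.diag([1, 1, dsign]) @ vt).T
    starts = [np.concatenate([Rotation.from_matrix(r0).as_rotvec(),
                              cr - cm @ r0.T])]
    for _ in range(24):
        rv = rng.normal(size=3)
        rot = Rotation.from_rotvec(rv).as_matrix()
        starts.append(np.concatenate([rv, cr - cm @ rot.T]))
    best = 0.0
    for s0 in starts:
        res = minimize(neg_tm, s0, method="Nelder-Mead",
                       options={"maxiter": 4000, "xatol": 1e-6, "fatol": 1e-10})
        best = max(best, -res.fun)
    print(best)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
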