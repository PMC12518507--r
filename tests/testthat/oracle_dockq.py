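"""Independent DockQ oracle: recomputes Fnat, iRMSD, LRMSD and the DockQ
score with NumPy from first principles, given native and predicted atom
tables (TSV: chain, seq_index, atom, x, y, z). Prints the score."""
import sys
import numpy as np

BACKBONE = ("N", "CA", "C", "O")


def load(path):
    rows = []
    with open(path) as fh:
        next(fh)
        for line in fh:
            ch, ri, at, x, y, z = line.split("\t")
            rows.append((ch, int(ri), at, float(x), float(y), float(z)))
    return rows


def coords(rows, chain, atoms=None, residues=None):
    sel = [r for r in rows if r[0] == chain
           and (atoms is None or r[2] in atoms)
           and (residues is None or r[1] in residues)]
    key = [(r[1], r[2]) for r in sel]
    xyz = np.array([r[3:6] for r in sel])
    return key, xyz


def kabsch(ref, mov):
    cr, cm = ref.mean(0), mov.mean(0)
    h = (mov - cm).T @ (ref - cr)
    u, s, vt = np.linalg.svd(h)
    d = np.sign(np.linalg.det(u @ vt))
    rot = u @ np.diag([1, 1, d]) @ vt
    return rot, cr - cm @ rot


def contacts(rows, cutoff=5.0):
    _, rx = coords(rows, "R")
    rres = [r[1] for r in rows if r[0] == "R"]
    _, px = coords(rows, "P")
    pres = [r[1] for r in rows if r[0] == "P"]
    d = np.linalg.norm(rx[:, None, :] - px[None, :, :], axis=2)
    ij = np.argwhere(d < cutoff)
    return {(rres[i], pres[j]) for i, j in ij}


def matched(nat, prd, chain, atoms=None, residues=None):
    ka, xa = coords(nat, chain, atoms, residues)
    kb, xb = coords(prd, chain, atoms, residues)
    common = [k for k in ka if k in set(kb)]
    ia = [ka.index(k) for k in common]
    ib = [kb.index(k) for k in common]
    return xa[ia], xb[ib]


def main(nat_path, prd_path):
    nat, prd = load(nat_path), load(prd_path)
    nat_ct = contacts(nat)
    prd_ct = contacts(prd)
    fnat = len(nat_ct & prd_ct) / len(nat_ct)

    # native interface residues: any heavy atom within 10 A of other chain
    _, rx = coords(nat, "R")
    rres = [r[1] for r in nat if r[0] == "R"]
    _, px = coords(nat, "P")
    pres = [r[1] for r in nat if r[0] == "P"]
    d = np.linalg.norm(rx[:, None, :] - px[None, :, :], axis=2)
    ir = {rres[i] for i in np.where((d < 10).any(1))[0]}
    ip = {pres[j] for j in np.where((d < 10).any(0))[0]}

    na_r, pa_r = matched(nat, prd, "R", BACKBONE, ir)
    na_p, pa_p = matched(nat, prd, "P", BACKBONE, ip)
    a = np.vstack([na_r, na_p])
    b = np.vstack([pa_r, pa_p])
    rot, tr = kabsch(a, b)
    irmsd = np.sqrt(((b @ rot + tr - a) ** 2).sum(1).mean())

    ra, rb = matched(nat, prd, "R", BACKBONE)
    rot, tr = kabsch(ra, rb)
    pa, pb = matched(nat, prd, "P", BACKBONE)
    lrmsd = np.sqrt(((pb @ rot + tr - pa) ** 2).sum(1).mean())

    score = (fnat + 1 / (1 + (irmsd / 1.5) ** 2) + 1 / (1 + (lrmsd / 8.5) ** 2)) / 3
    print(score)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
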