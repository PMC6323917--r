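{"id": "900001", "sections": {"abstract": "MicroRNA-21 governs proliferation in renal cancer cells. We measured expression by qPCR in three cohorts.", "results": "MiR-21 targets PTEN and regulates proliferation. Overexpression of miR-21 inhibited apoptosis in human cell lines. Values were normalized and plotted against the calibration curve."}, "species": ["hsa"]}
{"id": "900002", "sections": {"abstract": "The let-7 family suppresses RAS in multiple tissues.", "results": "In mouse, let-7a represses Hmga2 and inhibits proliferation. Expression of let-7 was quantified by northern blot.", "discussion": "Human let-7b also targets RAS, suggesting a conserved regulatory axis."}, "species": ["hsa", "mmu"]}
{"id": "900003", "sections": {"abstract": "The bantam microRNA promotes tissue growth in Drosophila.", "results": "Bantam inhibits the pro-apoptotic gene hid and promotes proliferation in the wing disc."}, "species": ["dme"]}
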