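{
  "comment": "Untreated (diseased) IGF-1R network reconstruction. Interactions: IGF->IGF-1R->IRS-1->PI3k->Akt->ER-alpha activation cascade (catalytic, upstream place conserved); ER-alpha positive feedback onto IGF-1R (consumes active ER-alpha); ER-alpha inhibitory arcs on each TSG activation (p53, Mdm2, BRCA1); Mdm2 catalyses BRCA1 activation and mediates p53 degradation; first-order degradation on every signaling species. All mass-action rates 1, unit weights, thresholds 1. Initial markings: IGF 5 (stated); receptor/kinases 4, ER-alpha 3, TSGs 0.2-0.5 (calibrated once against the published qualitative table, then frozen).",
  "places": [
    {
      "name": "IGF",
      "initial": 5
    },
    {
      "name": "IGF-1R",
      "initial": 4
    },
    {
      "name": "IRS-1",
      "initial": 4
    },
    {
      "name": "PI3k",
      "initial": 4
    },
    {
      "name": "Akt",
      "initial": 4
    },
    {
      "name": "ER-alpha",
      "initial": 3
    },
    {
      "name": "p53",
      "initial": 0.2
    },
    {
      "name": "BRCA1",
      "initial": 0.5
    },
    {
      "name": "Mdm2",
      "initial": 0.5
    }
  ],
  "transitions": [
    {
      "name": "act_IGF-1R",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "act_IRS-1",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "act_PI3k",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "act_Akt",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "act_ER-alpha",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "fb_ER-alpha_IGF-1R",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "act_p53",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": true
    },
    {
      "name": "act_Mdm2",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": true
    },
    {
      "name": "act_BRCA1",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_p53_Mdm2",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_IGF-1R",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_IRS-1",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_PI3k",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_Akt",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_ER-alpha",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_p53",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_BRCA1",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    },
    {
      "name": "deg_Mdm2",
      "type": "mass_action",
      "k": 1,
      "Vmax": null,
      "Km": null,
      "source": false
    }
  ],
  "arcs": [
    {
      "place": "IGF",
      "transition": "act_IGF-1R",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "IGF",
      "transition": "act_IGF-1R",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "IGF-1R",
      "transition": "act_IGF-1R",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "IGF-1R",
      "transition": "act_IRS-1",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "IGF-1R",
      "transition": "act_IRS-1",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "IRS-1",
      "transition": "act_IRS-1",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "IRS-1",
      "transition": "act_PI3k",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "IRS-1",
      "transition": "act_PI3k",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "PI3k",
      "transition": "act_PI3k",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "PI3k",
      "transition": "act_Akt",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "PI3k",
      "transition": "act_Akt",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "Akt",
      "transition": "act_Akt",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "Akt",
      "transition": "act_ER-alpha",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "Akt",
      "transition": "act_ER-alpha",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "ER-alpha",
      "transition": "act_ER-alpha",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "ER-alpha",
      "transition": "fb_ER-alpha_IGF-1R",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "IGF-1R",
      "transition": "fb_ER-alpha_IGF-1R",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "p53",
      "transition": "act_p53",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "Mdm2",
      "transition": "act_Mdm2",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "Mdm2",
      "transition": "act_BRCA1",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "Mdm2",
      "transition": "act_BRCA1",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "BRCA1",
      "transition": "act_BRCA1",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "p53",
      "transition": "deg_p53_Mdm2",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "Mdm2",
      "transition": "deg_p53_Mdm2",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "Mdm2",
      "transition": "deg_p53_Mdm2",
      "direction": "post",
      "weight": 1
    },
    {
      "place": "IGF-1R",
      "transition": "deg_IGF-1R",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "IRS-1",
      "transition": "deg_IRS-1",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "PI3k",
      "transition": "deg_PI3k",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "Akt",
      "transition": "deg_Akt",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "ER-alpha",
      "transition": "deg_ER-alpha",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "p53",
      "transition": "deg_p53",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "BRCA1",
      "transition": "deg_BRCA1",
      "direction": "pre",
      "weight": 1
    },
    {
      "place": "Mdm2",
      "transition": "deg_Mdm2",
      "direction": "pre",
      "weight": 1
    }
  ],
  "inhibitory_arcs": [
    {
      "place": "ER-alpha",
      "transition": "act_p53",
      "threshold": 1
    },
    {
      "place": "ER-alpha",
      "transition": "act_Mdm2",
      "threshold": 1
    },
    {
      "place": "ER-alpha",
      "transition": "act_BRCA1",
      "threshold": 1
    }
  ]
}
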