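item_id,instrument,n_categories,a,b1,b2,b3,b4,b5,b6,fixed
oks_walking,OKS,5,1.330,-1.920,-1.103,0.675,2.323,,,TRUE
oks_standing,OKS,5,1.951,-2.515,-0.118,1.299,2.858,,,TRUE
oks_limping,OKS,5,1.280,-0.299,1.256,2.121,4.010,,,TRUE
oks_kneeling,OKS,5,1.387,-0.304,1.195,2.949,4.468,,,TRUE
oks_transport,OKS,5,1.887,-3.756,-0.984,0.947,2.050,,,TRUE
oks_work,OKS,5,2.548,-1.406,0.154,1.563,2.712,,,TRUE
oks_stairs,OKS,5,2.108,-2.119,-0.382,1.122,2.383,,,TRUE
oks_giveway,OKS,5,1.501,-1.713,-0.270,0.651,2.171,,,TRUE
oks_shopping,OKS,5,2.222,-1.206,-0.443,0.690,1.673,,,TRUE
oks_nightpain,OKS,5,1.221,-0.811,0.484,2.003,2.624,,,TRUE
oks_pain,OKS,5,1.677,0.019,2.314,3.415,4.514,,,TRUE
oks_washing,OKS,5,1.475,-4.283,-2.049,-0.327,0.734,,,TRUE
haas_activity,HAAS,7,0.828,-3.420,0.504,2.121,5.983,9.272,10.220,FALSE
haas_running,HAAS,5,1.022,2.064,4.453,7.680,9.535,,,FALSE
haas_walking,HAAS,6,1.067,-1.215,0.199,2.378,3.205,4.729,,FALSE
haas_stairs,HAAS,4,0.968,-3.366,2.803,5.994,,,,FALSE
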