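model,description,dbar,dhat,pd,dic
1,intercept + road density with coefficient,3015.580,3013.600,1.985,3017.570
2,intercept + road density without coefficient,3283.520,3282.530,0.995,3284.520
3,intercept + unstructured component,328.936,283.227,45.709,374.646
4,intercept + structured component,334.725,291.671,43.054,377.779
5,intercept + unstructured + structured component,316.465,273.777,42.688,359.153
6,intercept + road density + structured + unstructured,356.994,306.799,50.195,407.189
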