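algorithm,predicted,walking,running,jumping
rf,walking,480,6,10
rf,running,2,163,14
rf,jumping,9,39,799
svm_rbf,walking,480,8,20
svm_rbf,running,1,185,17
svm_rbf,jumping,10,15,786
knn,walking,482,9,35
knn,running,0,185,24
knn,jumping,9,14,764
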