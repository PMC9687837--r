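study,candidate,accuracy,complexity_m,epoch_s
rsf,With RSF,95.59,434.5,77
rsf,Without RSF,95.01,657.3,84
filter_size,3 x 3,95.59,434.5,77
filter_size,2 x 2,95.04,327.4,71
filter_size,5 x 5,95.894,717.4,85
n_filters,16,95.23,286.24,74
n_filters,32,95.59,290.4,77
n_filters,64,96.29,294.4,78
pooling,Max,96.29,294.4,77
pooling,Average,96.29,294.4,77
activation,PReLU,97.28,294.4,77
activation,ReLU,96.29,294.4,77
activation,LeakyReLU,95.55,294.4,77
activation,Tanh,96.11,294.4,77
activation,ELU,96.29,294.4,77
batch_size,16,97.53,294.4,77
batch_size,32,97.78,294.4,77
batch_size,64,97.28,294.4,78
batch_size,128,96.78,294.4,78
head,Flatten,97.89,294.4,77
head,Global max-pooling,97.02,294.4,78
head,Global average pooling,97.35,294.4,77
loss,Binary cross-entropy,96.37,294.4,78
loss,Categorical cross-entropy,97.89,294.4,77
loss,Mean squared error,96.73,294.4,77
loss,Mean absolute error,97.37,294.4,78
loss,Mean squared logarithmic error,96.81,294.4,78
loss,Kullback-Leibler divergence,97.78,294.4,78
optimizer,Adam,98.03,294.4,77
optimizer,Nadam,96.94,294.4,77
optimizer,SGD,96.58,297.5,78
optimizer,Adamax,97.89,294.4,77
optimizer,RMSprop,96.08,294.4,79
learning_rate,0.01,96.67,294.4,77
learning_rate,0.007,97.46,294.4,77
learning_rate,0.001,98.03,294.4,77
learning_rate,0.0007,98.34,294.4,78
learning_rate,0.0001,97.83,294.4,78
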